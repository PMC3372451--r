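# Shared fixtures, built in code.

# two-leaf instance in which the two transcripts differ only by an exon
# gained constitutively at the gene level on the connecting path
fig_two_leaf_instance <- function() {
  tr <- as_gene_tree(ape::read.tree(text = "(X,Y)R;"))
  ts_instance(tr, list(
    X = matrix(c(1L, 0L), 1, 2, dimnames = list("tX", c("e1", "e2"))),
    Y = matrix(c(1L, 1L), 1, 2, dimnames = list("tY", c("e1", "e2")))))
}

# the worked guide-tree example: gene tree A(B(D,E),C(F,G)); two ancestral
# transcripts at A (one spanning D,E,F,G, one spanning D,F), one transcript
# born at B and at C with the single-left-child shape, new transcripts born
# at E and G
guide_tree_example <- function() {
  tr <- as_gene_tree(ape::read.tree(text = "((D,E)B,(F,G)C)A;"))
  cat <- shape_catalog(tr)
  topo <- topology(cat, c("A(B(D,E),C(F,G))", "A(B(D,-),C(F,-))",
                          "B(D,-)", "C(F,-)", "E", "G"))
  list(tree = tr, catalog = cat, topology = topo)
}

# small simulated instance with bounded transcript counts (no births keeps
# every leaf at <= n_T transcripts, within reach of the exhaustive oracle)
small_sim <- function(seed, n_leaves = 3, n_T = 2, n_E = 4,
                      caterpillar = TRUE, p_birth = 0) {
  tr <- if (caterpillar) make_caterpillar(n_leaves) else make_balanced(n_leaves)
  cfg <- sim_config(n_E = n_E, n_T = n_T,
                    p_exon_birth = 0.08, p_exon_death = 0.08,
                    p_gain = 0.12, p_loss = 0.12,
                    p_t_death = 0.05, p_t_birth = p_birth)
  simulate_instance(tr, cfg, seed = seed)
}

# brute force over all Dollo-consistent labelings of one column
brute_dollo_column <- function(tree, leaf_state) {
  n <- length(tree$label)
  internals <- which(!tree$is_leaf)
  leaves <- which(tree$is_leaf)
  best <- Inf
  labs <- list()
  grid <- expand.grid(rep(list(0:2), length(internals)))
  for (r in seq_len(nrow(grid))) {
    full <- integer(n)
    full[leaves] <- leaf_state
    full[internals] <- as.integer(unlist(grid[r, ]))
    gains <- if (full[tree$root] != 0) 1L else 0L
    cost <- 0
    for (v in seq_len(n)) {
      p <- tree$parent[v]
      if (is.na(p)) next
      if (full[p] != full[v]) cost <- cost + 1
      if (full[p] == 0 && full[v] != 0) gains <- gains + 1L
    }
    if (gains > 1L) next
    if (cost < best) { best <- cost; labs <- list(full) }
    else if (cost == best) labs[[length(labs) + 1L]] <- full
  }
  list(cost = best, labelings = labs)
}

expect_same_key_set <- function(a, b) {
  expect_setequal(vapply(a, canonical_key, ""), vapply(b, canonical_key, ""))
}
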