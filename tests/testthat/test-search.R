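test_that("the total score composes structural and parsimony parts", {
  co <- ts_costs(1, 1, 1)
  expect_equal(score_solution(2, 1, 3, co), 6)
  expect_identical(score_solution(1, 0, Inf, co), Inf)
  expect_equal(score_solution(1, 0, 0, ts_costs(7, 1, 1)), 7)
})

test_that("the similarity index matches its worked values", {
  expect_equal(similarity_index(rbind(c(1, 1, 0), c(1, 1, 0))), 1)  # shared
  expect_equal(similarity_index(rbind(c(1, 0), c(0, 1))), 0)        # unique
  expect_equal(similarity_index(rbind(c(1, 1), c(1, 0))), 0.5)      # {A,B},{A}
  expect_equal(similarity_index(rbind(c(0, 0), c(0, 0))), 1)        # no exons
  expect_error(similarity_index(matrix(0, 0, 2)), "leaf")
})

test_that("the lower bound never exceeds the per-topology optimum", {
  set.seed(55)
  costs <- ts_costs()
  for (rep in 1:12) {
    sim <- small_sim(800 + rep, n_leaves = sample(2:3, 1), n_T = sample(1:2, 1))
    inst <- sim$instance
    anc <- reconstruct_ancestral_exon_states(inst$tree, leaf_exon_states(inst))
    Z <- spliceforest:::zero_cost_mask(anc, inst$tree)
    counts <- vapply(inst$transcripts, nrow, 1L)
    cache <- new.env(parent = emptyenv())
    for (tp in enumerate_topologies(inst$tree, counts)) {
      lb <- topology_lower_bound(tp, inst, anc, costs, cache)
      opt <- spliceforest:::oracle_topology_optimum(tp, inst, anc, Z, costs)
      expect_lte(lb, opt$S + 1e-9)
      if (n_trees(tp) == 1)  # a single tree does not compete for transcripts
        expect_equal(lb, opt$S)
    }
  }
})

test_that("sampling gives a reproducible upper bound above the optimum", {
  sim <- small_sim(901, n_leaves = 3, n_T = 2)
  inst <- sim$instance
  u1 <- sample_initial_upper_bound(inst, ts_costs(), 3, seed = 5)
  u2 <- sample_initial_upper_bound(inst, ts_costs(), 3, seed = 5)
  expect_identical(u1, u2)
  bf <- brute_force_optimal(inst, ts_costs())
  expect_gte(u1, bf$score)
})

test_that("identical single transcripts at two leaves give one tree at c_B", {
  tr <- as_gene_tree(ape::read.tree(text = "(X,Y)R;"))
  inst <- ts_instance(tr, list(
    X = matrix(c(1L, 1L), 1, 2, dimnames = list("x", NULL)),
    Y = matrix(c(1L, 1L), 1, 2, dimnames = list("y", NULL))))
  res <- infer_transcript_phylogenies(inst, ts_costs(3, 1, 1))
  expect_equal(res$score, 3)
  expect_equal(res$n_solutions, 1L)
  expect_equal(res$solutions[[1]]$N_tree, 1)
  expect_equal(res$solutions[[1]]$N_death, 0)
})

test_that("pruning does not change the minimum or the solution set", {
  set.seed(66)
  for (rep in 1:6) {
    sim <- small_sim(950 + rep, n_leaves = sample(2:3, 1), n_T = sample(1:2, 1))
    inst <- sim$instance
    r1 <- infer_transcript_phylogenies(inst, ts_costs(), seed = rep, prune = TRUE)
    r2 <- infer_transcript_phylogenies(inst, ts_costs(), seed = rep, prune = FALSE)
    expect_equal(r1$score, r2$score)
    expect_setequal(vapply(r1$solutions, function(s) s$key, ""),
                    vapply(r2$solutions, function(s) s$key, ""))
  }
})

test_that("all returned solutions have exactly the minimum score", {
  sim <- small_sim(971, n_leaves = 3, n_T = 2)
  res <- infer_transcript_phylogenies(sim$instance, ts_costs(), seed = 1)
  for (s in res$solutions) expect_equal(s$S, res$score)
  # ranking: non-increasing mean similarity
  ms <- vapply(res$solutions, function(s) s$mean_similarity, 0)
  expect_true(!is.unsorted(rev(ms)))
  # components recompose the score
  for (s in res$solutions)
    expect_equal(s$S, score_solution(s$N_tree, s$N_death, s$S_F, res$costs))
})

test_that("an irreconcilable instance under c_E = Inf reports no solution", {
  tr <- as_gene_tree(ape::read.tree(text = "(X,Y)R;"))
  # every transcript of X carries an exon that is absent at the root and
  # gained as alternative on the edge to X, so any tree spanning that edge
  # has infinite cost and the gene graph cannot be connected
  inst <- ts_instance(tr, list(
    X = matrix(c(1L, 0L, 1L,
                 0L, 1L, 1L), 2, 3, byrow = TRUE,
               dimnames = list(c("x1", "x2"), c("e1", "e2", "e3"))),
    Y = matrix(c(0L, 0L, 1L), 1, 3, dimnames = list("y", c("e1", "e2", "e3")))))
  res <- infer_transcript_phylogenies(inst, ts_costs(1, 1, Inf))
  expect_identical(res$status, "no_solution")
  expect_identical(res$score, Inf)
  # with a finite change cost the same instance is solvable
  res2 <- infer_transcript_phylogenies(inst, ts_costs(1, 1, 1))
  expect_identical(res2$status, "ok")
})

test_that("extended model links newborns to their closest ancestor", {
  tr <- as_gene_tree(ape::read.tree(text = "(X,Y)R;"))
  inst <- ts_instance(tr, list(
    X = matrix(c(1L, 0L, 1L, 1L), 2, 2, byrow = TRUE,
               dimnames = list(c("x1", "x2"), c("e1", "e2"))),
    Y = matrix(c(1L, 0L), 1, 2, dimnames = list("y1", c("e1", "e2")))))
  res <- infer_transcript_phylogenies(inst, ts_costs(1, 1, 1), extended = TRUE)
  expect_identical(res$status, "ok")
  # every topology is visited: no pruning in the extended search
  counts <- vapply(inst$transcripts, nrow, 1L)
  expect_equal(sum(res$stats$generated),
               length(enumerate_topologies(inst$tree, counts)))
  s <- res$solutions[[1]]
  # the newborn differs from its closest ancestor by one column at c_E = 1
  expect_true(any(abs(s$birth_costs - 1) < 1e-9))
  # a newborn identical to an ancestral transcript costs nothing
  sol <- list(trees = list(
    list(gene = "R", vector = c(1L, 0L),
         left = list(gene = "X", vector = c(1L, 0L), transcript = "x1"),
         right = list(gene = "Y", vector = c(1L, 0L), transcript = "y1")),
    list(gene = "X", vector = c(1L, 0L), transcript = "x2")),
    N_death = 0, S_F = 0)
  ext <- extended_birth_cost(sol, tr, ts_costs(1, 1, 1))
  expect_equal(ext$birth_costs[2], 0)
})

test_that("results serialize to JSON with scores and tree strings", {
  sim <- small_sim(990, n_leaves = 2, n_T = 2)
  res <- infer_transcript_phylogenies(sim$instance, ts_costs(), seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_results(res, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$score, res$score)
  expect_equal(length(parsed$solutions), length(res$solutions))
  expect_true(all(c("S", "S_F", "N_tree", "N_death", "trees") %in%
                  names(parsed$solutions[[1]])))
})
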