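test_that("tree and death counts are recomputable from the forest structure", {
  gx <- guide_tree_example()
  expect_equal(n_trees(gx$topology), 6)
  # deaths: A(B(D,-),C(F,-)) has 2, B(D,-) and C(F,-) one each
  expect_equal(n_deaths(gx$topology), 4)
  expect_true(is_valid_topology(gx$topology))
})

test_that("edge removal adds one tree and one death; bare root slots allowed", {
  tr <- as_gene_tree(ape::read.tree(text = "(B,C)A;"))
  topo <- topology(shape_catalog(tr), "A(B,C)")
  r1 <- remove_edge(topo, 1, "B")
  expect_equal(n_trees(r1), 2)
  expect_equal(n_deaths(r1), 1)
  # removing the remaining link leaves a childless root slot: 3 trees, 2 deaths
  ix <- which(sort(r1$cat$key[r1$ids]) == "A(-,C)")
  r2 <- remove_edge(r1, ix, "C")
  expect_equal(n_trees(r2), 3)
  expect_equal(n_deaths(r2), 2)
  expect_error(remove_edge(topo, 1, "A"), "root")
  expect_error(remove_edge(topo, 5, "B"), "no such tree")
})

test_that("branch swap exchanges subtrees, preserving tree and death counts", {
  tr <- as_gene_tree(ape::read.tree(text = "((D,E)B,(F,G)C)A;"))
  ct <- shape_catalog(tr)
  tp <- topology(ct, c("A(B(D,-),C(F,G))", "A(B(D,E),-)"))
  sw <- branch_swap(tp, list(1, "B"), list(2, "B"))
  expect_equal(canonical_key(sw), "A(B(D,-),-)|A(B(D,E),C(F,G))")
  expect_equal(n_trees(sw), n_trees(tp))
  expect_equal(n_deaths(sw), n_deaths(tp))
  # swapping a link with itself is the identity
  expect_equal(canonical_key(branch_swap(tp, list(1, "B"), list(1, "B"))),
               canonical_key(tp))
  expect_error(branch_swap(tp, list(1, "B"), list(1, "C")), "same gene")
})

test_that("canonical keys identify topologies up to slot permutation", {
  tr <- as_gene_tree(ape::read.tree(text = "(B,C)A;"))
  ct <- shape_catalog(tr)
  t1 <- topology(ct, c("A(B,-)", "A(-,C)"))
  t2 <- topology(ct, c("A(-,C)", "A(B,-)"))  # same multiset, different order
  expect_identical(canonical_key(t1), canonical_key(t2))
  t3 <- topology(ct, c("A(B,C)"))
  expect_false(canonical_key(t1) == canonical_key(t3))
  # removing either symmetric link of two parallel spanning trees gives the
  # same canonical key
  tp <- topology(ct, c("A(B,C)", "A(B,C)"))
  ra <- remove_edge(tp, 1, "B")
  rb <- remove_edge(tp, 2, "B")
  expect_identical(canonical_key(ra), canonical_key(rb))
})

test_that("validity requires every gene hosted and gene-graph connectivity", {
  tr <- as_gene_tree(ape::read.tree(text = "(B,C)A;"))
  ct <- shape_catalog(tr)
  # both leaf transcripts newborn, no root slots: A unhosted -> invalid
  expect_false(is_valid_topology(topology(ct, c("B", "C"))))
  # right leaf hosts only a newborn: gene C is disconnected from the rest of
  # the gene graph (on a tree, connectivity means every gene-tree edge is
  # spanned by at least one slot link)
  expect_false(is_valid_topology(topology(ct, c("A(B,-)", "C"))))
  expect_true(is_valid_topology(topology(ct, c("A(B,-)", "A(-,C)"))))
  expect_true(is_valid_topology(topology(ct, c("A(B,C)"))))
})

test_that("enumeration agrees with the independent brute-force enumerator", {
  tr <- as_gene_tree(ape::read.tree(text = "(B,C)A;"))
  for (counts in list(c(B = 1L, C = 1L), c(B = 2L, C = 1L), c(B = 2L, C = 2L))) {
    expect_same_key_set(enumerate_topologies(tr, counts),
                        enumerate_topologies_bruteforce(tr, counts))
  }
  tr3 <- make_caterpillar(3)
  counts <- c(g1 = 2L, g2 = 1L, g3 = 2L)
  main <- enumerate_topologies(tr3, counts)
  expect_same_key_set(main, enumerate_topologies_bruteforce(tr3, counts))
  # no duplicate keys; groups ordered by increasing tree count
  keys <- vapply(main, canonical_key, "")
  expect_false(any(duplicated(keys)))
  expect_true(!is.unsorted(vapply(main, n_trees, 1L)))
  # every topology matches the requested leaf counts and is valid
  for (tp in main) {
    expect_true(is_valid_topology(tp))
    expect_true(spliceforest:::matches_leaf_counts(tp, counts))
  }
})

test_that("edge-removal products and swap closures stay inside the stream", {
  tr <- make_caterpillar(3)
  counts <- c(g1 = 1L, g2 = 1L, g3 = 1L)
  all_keys <- vapply(enumerate_topologies(tr, counts), canonical_key, "")
  t_of <- vapply(enumerate_topologies(tr, counts), n_trees, 1L)
  for (tp in enumerate_topologies(tr, counts)) {
    links <- spliceforest:::topology_links(tp)
    for (r in seq_len(nrow(links))) {
      child <- remove_edge(tp, links$tree[r], links$child[r])
      expect_equal(n_trees(child), n_trees(tp) + 1L)
      # products with childless internal slots are deliberately outside the
      # enumerated stream; all others must be in it
      if (all(child$cat$proper[child$ids]) && is_valid_topology(child))
        expect_true(canonical_key(child) %in% all_keys)
      # swapping is closed within the same tree count
      for (r2 in seq_len(nrow(links))) {
        if (links$child[r] != links$child[r2]) next
        sw <- branch_swap(tp, list(links$tree[r], links$child[r]),
                          list(links$tree[r2], links$child[r2]))
        expect_equal(n_trees(sw), n_trees(tp))
        if (is_valid_topology(sw))
          expect_true(canonical_key(sw) %in% all_keys)
      }
    }
  }
})

test_that("guide tree groups slots by identical subtree shape", {
  gx <- guide_tree_example()
  gt <- build_guide_tree(gx$topology)
  b <- gt[["B"]]
  expect_setequal(b$shape, c("B(D,E)", "B(D,-)"))
  expect_equal(b$dots[b$shape == "B(D,-)"], 2L)  # two slots of that shape
  expect_equal(b$dots[b$shape == "B(D,E)"], 1L)
  expect_equal(sum(gt[["D"]]$dots), 3L)  # leaf gene: one box of leaf slots
  expect_equal(nrow(gt[["D"]]), 1L)
})

test_that("the topology-space count matches enumeration before connectivity", {
  tr <- make_caterpillar(3)
  counts <- c(g1 = 2L, g2 = 1L, g3 = 1L)
  space <- count_topology_space(tr, counts)
  # compare with a filter-free enumeration: all coverage-exact multisets
  ct <- shape_catalog(tr)
  need <- spliceforest:::check_leaf_counts(ct, counts)
  total <- 0L
  for (t in seq(max(need), sum(need))) {
    # count DFS completions without validity filtering
    ok <- which(ct$proper)
    lc <- do.call(rbind, ct$leafcover[ok])
    cnt <- 0L
    rec <- function(from, rem, left) {
      if (left == 0L) { if (sum(rem) == 0L) cnt <<- cnt + 1L; return(invisible(NULL)) }
      if (sum(rem) < left) return(invisible(NULL))
      for (i in seq(from, length(ok))) {
        if (any(lc[i, ] > rem)) next
        rec(i, rem - lc[i, ], left - 1L)
      }
    }
    rec(1L, need, t)
    total <- total + cnt
  }
  expect_equal(unname(sum(space)), total)
})
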