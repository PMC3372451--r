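# Leaf assignment: given a topology, map observed transcripts to the
# topology's leaf slots so that the sum of the trees' Sankoff parsimony
# scores, S_F, is minimal. A state of a gene is an ordered list of its
# transcript slots with pointers into one state of each child; the guide
# tree (slots grouped by subtree shape) constrains feasible pointers. The
# dynamic program commits, per state, to the profiles of its best child-state
# pair, which makes it a heuristic on gene trees of depth > 2; on trees of
# depth <= 2 an exhaustive search over state combinations is used instead.

#' Upper bound on the number of states at a gene
#'
#' Closed-form count of pointer assignments at a gene with \code{k_LR} slots
#' with two children, \code{k_L} with a single left child and \code{k_R}
#' with a single right child, when both child genes have \code{n} slots and
#' no guide-tree constraint applies:
#' \code{choose(n, k_LR) * n!/(n-k_LR)! * choose(n-k_LR, k_L) * choose(n-k_LR, k_R)}.
#'
#' @param n Number of slots in each child state.
#' @param k_LR,k_L,k_R Slot counts by child pattern.
#' @return The number of unconstrained states (numeric).
#' @export
count_states <- function(n, k_LR, k_L, k_R) {
  for (v in c(n, k_LR, k_L, k_R))
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != round(v))
      stop("arguments must be single non-negative integers", call. = FALSE)
  if (k_LR + k_L > n || k_LR + k_R > n)
    stop("k_LR + k_L and k_LR + k_R must not exceed n", call. = FALSE)
  choose(n, k_LR) * factorial(n) / factorial(n - k_LR) *
    choose(n - k_LR, k_L) * choose(n - k_LR, k_R)
}

# all ordered injections of `k` demands into the integer vector `targets`
injections <- function(targets, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  for (i in seq_along(targets)) {
    for (rest in injections(targets[-i], k - 1L)) {
      out[[length(out) + 1L]] <- c(targets[i], rest)
    }
  }
  out
}

# feasible pointer maps for one side (child gene `cv`) of gene `v`
side_states <- function(ti, v, side) {
  cat <- ti$topo$cat
  slots_v <- ti$slots_of_gene[[v]]
  cv <- if (side == "L") ti$tree$left[v] else ti$tree$right[v]
  slots_c <- ti$slots_of_gene[[cv]]
  child_of <- if (side == "L") ti$slot_left[slots_v] else ti$slot_right[slots_v]
  demand_pos <- which(!is.na(child_of))
  req_shape <- cat$key[ti$slot_shape[child_of[demand_pos]]]
  child_shape <- cat$key[ti$slot_shape[slots_c]]
  # per distinct required shape, injections into matching child slot positions
  ptr0 <- rep(NA_integer_, length(slots_v))
  if (!length(demand_pos)) return(list(ptr0))
  shapes <- unique(req_shape)
  per_shape <- list()
  for (s in shapes) {
    dem <- demand_pos[req_shape == s]
    tgt <- which(child_shape == s)
    if (length(tgt) < length(dem)) return(list())  # infeasible
    per_shape[[s]] <- list(dem = dem, inj = injections(tgt, length(dem)))
  }
  maps <- list(ptr0)
  for (s in shapes) {
    new_maps <- list()
    for (m in maps) for (inj in per_shape[[s]]$inj) {
      m2 <- m
      m2[per_shape[[s]]$dem] <- inj
      new_maps[[length(new_maps) + 1L]] <- m2
    }
    maps <- new_maps
  }
  maps
}

# all states of gene v in an instantiated topology.
# leaf gene: assignments of observed transcripts to slots. All k! orderings
# are states in principle, but leaf slots share a single guide-tree box, so
# the parent's pointer injections (and the complement choice of root slots)
# already realize every assignment: only the identity ordering is kept, an
# exact symmetry reduction.
# internal gene: cross product of feasible left and right pointer maps.
states_for_gene <- function(ti, v, instance = NULL, max_states = 100000,
                            all_leaf_orderings = FALSE) {
  tree <- ti$tree
  slots_v <- ti$slots_of_gene[[v]]
  if (!length(slots_v) && !tree$is_leaf[v]) {
    # a gene no tree passes through (invalid topologies only): one empty state
    return(list(list(ptrL = integer(0), ptrR = integer(0))))
  }
  if (tree$is_leaf[v]) {
    k <- length(slots_v)
    tmat <- instance$transcripts[[tree$label[v]]]
    if (!is.null(tmat) && nrow(tmat) != k)
      stop("leaf slot count does not match transcript count at gene ",
           tree$label[v], call. = FALSE)
    if (!all_leaf_orderings) return(list(list(assign = seq_len(k))))
    perms <- injections(seq_len(k), k)
    return(lapply(perms, function(p) list(assign = p)))
  }
  ls <- side_states(ti, v, "L")
  rs <- side_states(ti, v, "R")
  if (!length(ls) || !length(rs)) return(list())
  if (length(ls) * length(rs) > max_states)
    stop("state space at gene ", tree$label[v], " exceeds max_states", call. = FALSE)
  out <- vector("list", length(ls) * length(rs))
  i <- 0L
  for (a in ls) for (b in rs) { i <- i + 1L; out[[i]] <- list(ptrL = a, ptrR = b) }
  # slots of identical subtree shape are interchangeable: two states that
  # differ only by permuting such slots (with their pointers) describe the
  # same forest, so keep one canonical representative per class
  box <- ti$topo$cat$key[ti$slot_shape[slots_v]]
  keys <- vapply(out, function(s) {
    pair <- paste(s$ptrL, s$ptrR, sep = ":")
    paste(vapply(split(pair, box), function(p) paste(sort(p), collapse = ","), ""),
          collapse = ";")
  }, "")
  out[!duplicated(keys)]
}

#' Enumerate guide-tree-compatible states at a gene
#'
#' Lists every feasible pointer assignment at \code{gene}: each slot with a
#' left (right) child must point to a distinct slot of the left (right)
#' child gene whose subtree shape matches, as recorded in the guide tree.
#' Which particular state the child genes are in does not change the set of
#' feasible pointer patterns, so \code{left_state}/\code{right_state} are
#' accepted for interface compatibility and ignored.
#'
#' @param topo A \code{ts_topology}.
#' @param gene Gene label.
#' @param guide Optional \code{guide_tree} (recomputed if missing).
#' @param left_state,right_state Ignored (see above).
#' @return A list of states; for an internal gene each state has integer
#'   pointer vectors \code{ptrL}, \code{ptrR} (positions in the child genes'
#'   slot lists, \code{NA} where a slot has no child on that side).
#' @export
enumerate_states <- function(topo, gene, guide = NULL,
                             left_state = NULL, right_state = NULL) {
  ti <- instantiate_topology(topo)
  v <- node_index(ti$tree, gene)
  states_for_gene(ti, v, all_leaf_orderings = TRUE)
}

# ---- profiles --------------------------------------------------------------

# child-side Sankoff contribution. childprof: columns x configs matrix;
# zero_rows: columns where the gene-level event makes any change free.
row_mins <- function(m) {
  out <- m[, 1]
  nc <- ncol(m)
  if (nc > 1) for (j in 2:nc) out <- pmin(out, m[, j])
  out
}

child_contrib <- function(childprof, zero_rows, c_E) {
  m0 <- row_mins(childprof)
  if (is.finite(c_E)) {
    out <- pmin(childprof, m0 + c_E)
  } else {
    out <- childprof
  }
  if (any(zero_rows)) out[zero_rows, ] <- m0[zero_rows]
  out
}

# profile of one slot at internal gene v from its pointed children's profiles
slot_profile <- function(v, profL, profR, ancestral, Z, tree, alphabet, c_E) {
  ncols <- length(alphabet)
  A <- max(alphabet)
  t <- matrix(0, nrow = ncols, ncol = A + 1L)
  if (!is.null(profL)) {
    zl <- Z[tree$left[v], ]
    t <- t + child_contrib(profL, zl, c_E)
  }
  if (!is.null(profR)) {
    zr <- Z[tree$right[v], ]
    t <- t + child_contrib(profR, zr, c_E)
  }
  # configurations outside the column alphabet are never available
  for (u in seq_len(A)) t[alphabet < u, u + 1L] <- Inf
  # a transcript cannot include an exon absent from its gene
  absent <- ancestral[v, ] == EXON_ABSENT
  if (any(absent)) t[absent, -1L] <- Inf
  t
}

leaf_profile <- function(vec, alphabet) {
  ncols <- length(alphabet)
  A <- max(alphabet)
  t <- matrix(Inf, nrow = ncols, ncol = A + 1L)
  t[cbind(seq_len(ncols), vec + 1L)] <- 0
  t
}

min_mp <- function(prof) sum(row_mins(prof))

# profiles of all slots of gene v under a fixed state, given child profiles
gene_profiles <- function(ti, v, state, profs_L, profs_R, instance, ancestral,
                          Z, costs) {
  tree <- ti$tree
  slots_v <- ti$slots_of_gene[[v]]
  out <- vector("list", length(slots_v))
  if (tree$is_leaf[v]) {
    tmat <- instance$transcripts[[tree$label[v]]]
    for (j in seq_along(slots_v))
      out[[j]] <- leaf_profile(tmat[state$assign[j], ], instance$alphabet)
    return(out)
  }
  for (j in seq_along(slots_v)) {
    pl <- if (!is.na(state$ptrL[j])) profs_L[[state$ptrL[j]]] else NULL
    pr <- if (!is.na(state$ptrR[j])) profs_R[[state$ptrR[j]]] else NULL
    out[[j]] <- slot_profile(v, pl, pr, ancestral, Z, tree,
                             instance$alphabet, costs$c_E)
  }
  out
}

# exact S_F of one full state combination (one state index per gene)
score_fixed_states <- function(ti, states, choice, instance, ancestral, Z, costs,
                               want_profiles = FALSE) {
  tree <- ti$tree
  profs <- vector("list", length(tree$label))
  total <- 0
  for (v in tree$postorder) {
    if (!length(ti$slots_of_gene[[v]])) { profs[[v]] <- list(); next }
    s <- states[[v]][[choice[v]]]
    pl <- if (!tree$is_leaf[v]) profs[[tree$left[v]]] else NULL
    pr <- if (!tree$is_leaf[v]) profs[[tree$right[v]]] else NULL
    profs[[v]] <- gene_profiles(ti, v, s, pl, pr, instance, ancestral, Z, costs)
  }
  for (v in seq_along(tree$label)) {
    sl <- ti$slots_of_gene[[v]]
    if (!length(sl)) next
    p <- tree$parent[v]
    pointed <- integer(0)
    if (!is.na(p) && length(ti$slots_of_gene[[p]])) {
      sp <- states[[p]][[choice[p]]]
      ptr <- if (tree$left[p] == v) sp$ptrL else sp$ptrR
      pointed <- ptr[!is.na(ptr)]
    }
    for (j in setdiff(seq_along(sl), pointed))
      total <- total + min_mp(profs[[v]][[j]])
  }
  if (want_profiles) list(SF = total, profiles = profs) else total
}

# ---- main entry ------------------------------------------------------------

#' Best leaf assignment for a topology
#'
#' Runs the state dynamic program (exhaustively over full state combinations
#' when the gene tree has depth <= 2, which makes the result exact there) and
#' returns the tree-parsimony score S_F together with every optimal
#' assignment found by backtracking.
#'
#' @param topo A \code{ts_topology} whose leaf slot counts match the
#'   instance's transcript counts.
#' @param instance A \code{ts_instance}.
#' @param ancestral Exon-state matrix from
#'   \code{\link{reconstruct_ancestral_exon_states}} (computed if missing).
#' @param costs A \code{ts_costs}.
#' @param max_solutions Cap on backtracked assignments.
#' @param exhaustive Force (TRUE) or forbid (FALSE) the exhaustive search;
#'   default \code{NULL} uses it iff the gene tree depth is <= 2.
#' @return A list with elements \code{S_F} (score, \code{Inf} when the
#'   topology admits no feasible assignment), \code{solutions} (list; each
#'   has one chosen state per gene) and \code{states} (the per-gene state
#'   lists, for inspection).
#' @export
assign_leaves <- function(topo, instance, ancestral = NULL, costs = ts_costs(),
                          max_solutions = 10000, exhaustive = NULL) {
  stopifnot(inherits(topo, "ts_topology"), inherits(instance, "ts_instance"))
  tree <- instance$tree
  counts <- vapply(instance$transcripts, nrow, 1L)
  if (!matches_leaf_counts(topo, counts))
    stop("topology leaf slot counts do not match observed transcript counts",
         call. = FALSE)
  if (is.null(ancestral))
    ancestral <- reconstruct_ancestral_exon_states(tree, leaf_exon_states(instance))
  Z <- zero_cost_mask(ancestral, tree)
  ti <- instantiate_topology(topo)
  states <- vector("list", length(tree$label))
  for (v in tree$postorder) {
    states[[v]] <- states_for_gene(ti, v, instance)
    if (!length(states[[v]]))
      return(list(S_F = Inf, solutions = list(), states = states))
  }
  if (is.null(exhaustive)) exhaustive <- tree_depth(tree) <= 2L
  if (exhaustive) {
    assign_exhaustive(ti, states, instance, ancestral, Z, costs, max_solutions)
  } else {
    assign_dp(ti, states, instance, ancestral, Z, costs, max_solutions)
  }
}

# exhaustive search over full state combinations (exact)
assign_exhaustive <- function(ti, states, instance, ancestral, Z, costs,
                              max_solutions, max_combos = 500000) {
  tree <- ti$tree
  active <- which(vapply(states, length, 1L) > 0L)
  sizes <- vapply(states[active], length, 1L)
  if (prod(sizes) > max_combos)
    stop("exhaustive state search too large (", prod(sizes), " combinations)",
         call. = FALSE)
  grid <- as.matrix(expand.grid(lapply(sizes, seq_len)))
  best <- Inf
  sols <- list()
  choice <- rep(1L, length(tree$label))
  for (i in seq_len(nrow(grid))) {
    choice[active] <- grid[i, ]
    sc <- score_fixed_states(ti, states, choice, instance, ancestral, Z, costs)
    if (sc < best - 1e-9) { best <- sc; sols <- list() }
    if (sc < best + 1e-9 && length(sols) < max_solutions)
      sols[[length(sols) + 1L]] <- choice
  }
  list(S_F = best, solutions = sols, states = states)
}

# bottom-up dynamic program with per-state profile commitment (heuristic for
# depth > 2); backtracked tie assignments are re-scored exactly and only
# those matching the best recomputed score are kept.
assign_dp <- function(ti, states, instance, ancestral, Z, costs, max_solutions) {
  tree <- ti$tree
  n <- length(tree$label)
  score_v <- vector("list", n)    # per state: committed score
  prof_v <- vector("list", n)     # per state: list of slot profiles
  mm_v <- vector("list", n)       # per state: minMP per slot
  back_v <- vector("list", n)     # per state: list of (iL, iR) tie pairs
  for (v in tree$postorder) {
    sts <- states[[v]]
    ns <- length(sts)
    if (tree$is_leaf[v]) {
      score_v[[v]] <- rep(0, ns)
      prof_v[[v]] <- lapply(sts, function(s)
        gene_profiles(ti, v, s, NULL, NULL, instance, ancestral, Z, costs))
      mm_v[[v]] <- t(vapply(prof_v[[v]], function(pp)
        vapply(pp, min_mp, 0), numeric(length(ti$slots_of_gene[[v]]))))
      if (length(ti$slots_of_gene[[v]]) == 1L) mm_v[[v]] <- matrix(mm_v[[v]], nrow = ns)
      back_v[[v]] <- rep(list(NULL), ns)
      next
    }
    L <- tree$left[v]; R <- tree$right[v]
    nl <- length(states[[L]]); nr <- length(states[[R]])
    score_v[[v]] <- numeric(ns)
    prof_v[[v]] <- vector("list", ns)
    back_v[[v]] <- vector("list", ns)
    mm_mat <- matrix(0, nrow = ns, ncol = length(ti$slots_of_gene[[v]]))
    for (is in seq_len(ns)) {
      s <- sts[[is]]
      unL <- setdiff(seq_along(ti$slots_of_gene[[L]]), s$ptrL[!is.na(s$ptrL)])
      unR <- setdiff(seq_along(ti$slots_of_gene[[R]]), s$ptrR[!is.na(s$ptrR)])
      costL <- score_v[[L]] +
        (if (length(unL)) rowSums(mm_v[[L]][, unL, drop = FALSE]) else 0)
      costR <- score_v[[R]] +
        (if (length(unR)) rowSums(mm_v[[R]][, unR, drop = FALSE]) else 0)
      bl <- min(costL); br <- min(costR)
      score_v[[v]][is] <- bl + br
      ties <- expand.grid(iL = which(costL < bl + 1e-9),
                          iR = which(costR < br + 1e-9))
      back_v[[v]][[is]] <- ties
      iL <- ties$iL[1]; iR <- ties$iR[1]
      prof_v[[v]][[is]] <- gene_profiles(ti, v, s, prof_v[[L]][[iL]],
                                         prof_v[[R]][[iR]], instance,
                                         ancestral, Z, costs)
      mm_mat[is, ] <- vapply(prof_v[[v]][[is]], min_mp, 0)
    }
    mm_v[[v]] <- mm_mat
  }
  rt <- tree$root
  totals <- score_v[[rt]] + rowSums(mm_v[[rt]])
  best <- min(totals)
  if (!is.finite(best)) return(list(S_F = Inf, solutions = list(), states = states))
  top_states <- which(totals < best + 1e-9)
  # backtrack all tie chains (capped), re-score exactly
  combos <- list()
  expand <- function(choice, v) {
    if (length(combos) >= max_solutions) return(invisible(NULL))
    if (tree$is_leaf[v]) return(list(choice))
    out <- list()
    ties <- back_v[[v]][[choice[v]]]
    L <- tree$left[v]; R <- tree$right[v]
    for (k in seq_len(nrow(ties))) {
      ch <- choice
      ch[L] <- ties$iL[k]; ch[R] <- ties$iR[k]
      subL <- expand(ch, L)
      for (cl in subL) {
        subR <- expand(cl, R)
        out <- c(out, subR)
        if (length(out) + length(combos) >= max_solutions) break
      }
      if (length(out) + length(combos) >= max_solutions) break
    }
    out
  }
  for (is in top_states) {
    choice <- rep(1L, n)
    choice[rt] <- is
    combos <- c(combos, expand(choice, rt))
    if (length(combos) >= max_solutions) break
  }
  if (length(combos) == 1L) {
    # the first chain realizes the committed DP score exactly
    return(list(S_F = best, solutions = combos, states = states))
  }
  exact <- vapply(combos, function(ch)
    score_fixed_states(ti, states, ch, instance, ancestral, Z, costs), 0)
  best_exact <- min(c(exact, best))
  keep <- which(exact < best_exact + 1e-9)
  list(S_F = best_exact, solutions = combos[keep], states = states)
}

#' Parsimony score of a completed slot profile
#'
#' Sum over exon columns of the minimum profile entry; \code{Inf} propagates
#' (meaningful when \code{c_E = Inf}).
#'
#' @param profile Numeric matrix (columns x configurations).
#' @return Non-negative score.
#' @export
minMP <- function(profile) min_mp(profile)
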