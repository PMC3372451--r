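# Topology-space search: scoring, lower bounds, sampling initialization,
# breadth-first exploration with pruning, solution ranking, extended model.

#' Total score of a solution
#'
#' \code{S = c_B * N_tree + c_D * N_death + S_F}: a constant cost per
#' transcript birth (tree) and death plus the sum of the trees' parsimony
#' scores. \code{Inf} propagates.
#'
#' @param n_tree,n_death,S_F Solution components.
#' @param costs A \code{ts_costs}.
#' @return Numeric score.
#' @export
score_solution <- function(n_tree, n_death, S_F, costs) {
  costs$c_B * n_tree + costs$c_D * n_death + S_F
}

#' Similarity index of a transcript tree
#'
#' Ranks co-optimal solutions: for one tree, sum over its leaves the number
#' of exons of that leaf that are included in at least two leaves, divided by
#' the number of exons included in at least one leaf times the number of
#' leaves. 1 when all leaves share the same exons (or the tree has no
#' included exon), 0 when every exon is unique to its leaf.
#'
#' @param leaf_vectors Integer matrix, one row per tree leaf, one column per
#'   exon column (0 = excluded).
#' @return Value in [0, 1].
#' @export
similarity_index <- function(leaf_vectors) {
  if (is.null(dim(leaf_vectors))) leaf_vectors <- matrix(leaf_vectors, nrow = 1)
  if (nrow(leaf_vectors) < 1) stop("similarity index needs >= 1 leaf", call. = FALSE)
  inc <- leaf_vectors >= 1
  present <- colSums(inc) >= 1
  shared <- colSums(inc) >= 2
  denom <- sum(present) * nrow(inc)
  if (denom == 0) return(1)
  sum(inc[, shared, drop = FALSE]) / denom
}

# relaxed parsimony profile of a shape, as if every transcript of each leaf
# gene were available to every slot (trees do not compete); memoised per
# shape id in `cache` (an environment)
shape_relaxed_profile <- function(cat, sid, instance, ancestral, Z, costs, cache) {
  key <- as.character(sid)
  if (!is.null(cache[[key]])) return(cache[[key]])
  tree <- cat$tree
  v <- cat$node[sid]
  alphabet <- instance$alphabet
  A <- max(alphabet); ncols <- length(alphabet)
  if (tree$is_leaf[v]) {
    tmat <- instance$transcripts[[tree$label[v]]]
    prof <- matrix(Inf, nrow = ncols, ncol = A + 1L)
    for (r in seq_len(nrow(tmat)))
      prof[cbind(seq_len(ncols), tmat[r, ] + 1L)] <- 0
  } else {
    prof <- matrix(0, nrow = ncols, ncol = A + 1L)
    l <- cat$left[sid]; r <- cat$right[sid]
    if (!is.na(l)) {
      pl <- shape_relaxed_profile(cat, l, instance, ancestral, Z, costs, cache)
      prof <- prof + child_contrib(pl, Z[tree$left[v], ], costs$c_E)
    }
    if (!is.na(r)) {
      pr <- shape_relaxed_profile(cat, r, instance, ancestral, Z, costs, cache)
      prof <- prof + child_contrib(pr, Z[tree$right[v], ], costs$c_E)
    }
    for (u in seq_len(A)) prof[alphabet < u, u + 1L] <- Inf
    absent <- ancestral[v, ] == EXON_ABSENT
    if (any(absent)) prof[absent, -1L] <- Inf
  }
  cache[[key]] <- prof
  prof
}

#' Lower bound on the score of any completion of a topology
#'
#' Structural part \code{c_B * N_tree + c_D * N_death} plus, per tree, the
#' best leaf assignment computed as if all transcripts were available to that
#' tree alone (trees do not compete for transcripts). Never exceeds the true
#' best score of any leaf assignment of the topology.
#'
#' @param topo A \code{ts_topology}.
#' @param instance A \code{ts_instance}.
#' @param ancestral Exon-state matrix (computed if missing).
#' @param costs A \code{ts_costs}.
#' @param cache Optional environment memoising per-shape relaxed scores
#'   across topologies of one search.
#' @return Numeric lower bound.
#' @export
topology_lower_bound <- function(topo, instance, ancestral = NULL,
                                 costs = ts_costs(), cache = NULL) {
  if (is.null(ancestral))
    ancestral <- reconstruct_ancestral_exon_states(instance$tree,
                                                   leaf_exon_states(instance))
  Z <- zero_cost_mask(ancestral, instance$tree)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  relaxed <- 0
  for (sid in topo$ids) {
    prof <- shape_relaxed_profile(topo$cat, sid, instance, ancestral, Z, costs, cache)
    relaxed <- relaxed + min_mp(prof)
  }
  score_solution(n_trees(topo), n_deaths(topo), relaxed, costs)
}

#' Initial upper bound by random sampling of the search space
#'
#' Draws, for each number of extra tree births on top of a random base
#' configuration, up to \code{samples_per_tree_count} random topologies
#' (random demand-driven construction followed by random edge removals),
#' scores each under a random leaf assignment, and returns the minimum score
#' seen. Deterministic given \code{seed}.
#'
#' @param instance A \code{ts_instance}.
#' @param costs A \code{ts_costs}.
#' @param samples_per_tree_count Samples per tree count (>= 1).
#' @param seed Integer seed.
#' @param catalog Optional prebuilt \code{shape_catalog}.
#' @param ancestral Optional exon-state matrix.
#' @param max_extra_removals Range of extra tree counts sampled above the
#'   base configuration.
#' @return Numeric upper bound (\code{Inf} when nothing could be scored).
#' @export
sample_initial_upper_bound <- function(instance, costs = ts_costs(),
                                       samples_per_tree_count = 3, seed = 1,
                                       catalog = NULL, ancestral = NULL,
                                       max_extra_removals = 2L) {
  stopifnot(samples_per_tree_count >= 1)
  counts <- vapply(instance$transcripts, nrow, 1L)
  if (is.null(catalog)) catalog <- shape_catalog(instance$tree)
  if (is.null(ancestral))
    ancestral <- reconstruct_ancestral_exon_states(instance$tree,
                                                   leaf_exon_states(instance))
  Z <- zero_cost_mask(ancestral, instance$tree)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  best <- Inf
  for (extra in 0:max_extra_removals) {
    for (s in seq_len(samples_per_tree_count)) {
      topo <- random_topology(catalog, counts, extra_removals = extra)
      if (is.null(topo) || !matches_leaf_counts(topo, counts)) next
      ti <- instantiate_topology(topo)
      states <- lapply(seq_along(instance$tree$label), function(v)
        states_for_gene(ti, v, instance))
      choice <- vapply(states, function(st) sample.int(length(st), 1L), 1L)
      sf <- score_fixed_states(ti, states, choice, instance, ancestral, Z, costs)
      best <- min(best, score_solution(n_trees(topo), n_deaths(topo), sf, costs))
    }
  }
  best
}

# ---- solution construction -------------------------------------------------

# turn one full state combination into a concrete forest with ancestral
# transcript vectors, per-tree serializations and summary quantities
build_solution <- function(ti, states, choice, instance, ancestral, Z, costs) {
  tree <- ti$tree
  res <- score_fixed_states(ti, states, choice, instance, ancestral, Z, costs,
                            want_profiles = TRUE)
  profs <- res$profiles
  st <- lapply(seq_along(tree$label), function(v) states[[v]][[choice[v]]])

  pointed_of <- function(v) {
    p <- tree$parent[v]
    if (is.na(p)) return(integer(0))
    sp <- st[[p]]
    ptr <- if (tree$left[p] == v) sp$ptrL else sp$ptrR
    ptr[!is.na(ptr)]
  }

  n_changes <- 0
  build_node <- function(v, j, cfg) {
    # cfg: configuration vector chosen for this slot
    node <- list(gene = tree$label[v], vector = cfg)
    if (tree$is_leaf[v]) {
      tmat <- instance$transcripts[[tree$label[v]]]
      node$transcript <- rownames(tmat)[st[[v]]$assign[j]]
      return(node)
    }
    for (side in c("left", "right")) {
      ptr <- if (side == "left") st[[v]]$ptrL[j] else st[[v]]$ptrR[j]
      if (is.na(ptr)) next
      cv <- if (side == "left") tree$left[v] else tree$right[v]
      childprof <- profs[[cv]][[ptr]]
      zr <- Z[cv, ]
      ccfg <- integer(length(cfg))
      for (i in seq_along(cfg)) {
        u <- cfg[i]
        opts <- childprof[i, ]
        tr <- rep(costs$c_E, length(opts))
        tr[u + 1L] <- 0
        if (zr[i]) tr[] <- 0
        ccfg[i] <- which.min(tr + opts) - 1L
      }
      n_changes <<- n_changes + sum(ccfg != cfg)
      node[[side]] <- build_node(cv, ptr, ccfg)
    }
    node
  }

  trees <- list()
  for (v in seq_along(tree$label)) {
    sl <- ti$slots_of_gene[[v]]
    if (!length(sl)) next
    for (j in setdiff(seq_along(sl), pointed_of(v))) {
      prof <- profs[[v]][[j]]
      cfg <- apply(prof, 1, which.min) - 1L
      trees[[length(trees) + 1L]] <- build_node(v, j, as.integer(cfg))
    }
  }

  tree_string <- function(nd) {
    if (!is.null(nd$transcript)) return(paste0(nd$gene, "=", nd$transcript))
    if (is.null(nd$left) && is.null(nd$right)) return(paste0(nd$gene, "(-,-)"))
    paste0(nd$gene, "(",
           if (is.null(nd$left)) "-" else tree_string(nd$left), ",",
           if (is.null(nd$right)) "-" else tree_string(nd$right), ")")
  }
  tree_leaf_vectors <- function(nd) {
    if (!is.null(nd$transcript)) return(matrix(nd$vector, nrow = 1))
    do.call(rbind, c(
      if (!is.null(nd$left)) list(tree_leaf_vectors(nd$left)),
      if (!is.null(nd$right)) list(tree_leaf_vectors(nd$right))))
  }
  strs <- vapply(trees, tree_string, "")
  ord <- order(strs)
  trees <- trees[ord]; strs <- strs[ord]
  sims <- vapply(trees, function(nd) {
    lv <- tree_leaf_vectors(nd)
    if (is.null(lv)) 1 else similarity_index(lv)
  }, 0)
  topo <- ti$topo
  list(S_F = res$SF,
       N_tree = n_trees(topo), N_death = n_deaths(topo),
       S = score_solution(n_trees(topo), n_deaths(topo), res$SF, costs),
       trees = trees, tree_strings = strs,
       key = paste(strs, collapse = " | "),
       similarity = sims, mean_similarity = mean(sims),
       n_changes = n_changes,
       topology_key = canonical_key(topo))
}

#' Extended-model birth cost of a solution
#'
#' Replaces the constant birth cost of each tree by the transcript-level
#' change cost between the newborn root's reconstructed exon vector and its
#' closest (least-cost) ancestor: the nearest other transcript vector in the
#' solution found at the root's gene or any of its ancestor genes. A tree
#' with no candidate ancestor (e.g. the only tree at the gene-tree root)
#' keeps the constant cost \code{c_B}. Death costs are unchanged.
#'
#' @param sol A solution record as produced by the search.
#' @param tree The \code{gene_tree}.
#' @param costs A \code{ts_costs}.
#' @return List with \code{birth_costs} (per tree) and \code{S_extended}
#'   (\code{c_D * N_death + S_F + sum(birth_costs)}).
#' @export
extended_birth_cost <- function(sol, tree, costs) {
  k <- length(sol$trees)
  birth <- numeric(k)
  for (i in seq_len(k)) {
    root_gene <- sol$trees[[i]]$gene
    anc <- c(root_gene, tree$label[node_ancestors(tree, node_index(tree, root_gene))])
    cands <- list()
    grab <- function(nd) {
      if (nd$gene %in% anc) cands[[length(cands) + 1L]] <<- nd$vector
      if (!is.null(nd$left)) grab(nd$left)
      if (!is.null(nd$right)) grab(nd$right)
    }
    for (j in setdiff(seq_len(k), i)) grab(sol$trees[[j]])
    if (!length(cands)) { birth[i] <- costs$c_B; next }
    d <- vapply(cands, function(v) sum(v != sol$trees[[i]]$vector), 0)
    birth[i] <- costs$c_E * min(d)
    if (min(d) == 0) birth[i] <- 0  # avoid Inf * 0 when c_E is infinite
  }
  list(birth_costs = birth,
       S_extended = costs$c_D * sol$N_death + sol$S_F + sum(birth))
}

# ---- main search -----------------------------------------------------------

#' Infer all minimum-cost transcript phylogenies
#'
#' Reconstructs ancestral exon states, enumerates transcript-forest
#' topologies by increasing tree count, prunes topologies whose lower bound
#' exceeds the best score seen so far (initialised by random sampling), runs
#' the leaf assignment on the survivors, and returns every solution achieving
#' the global minimum, ranked by the secondary criteria (minimum number of
#' events, then decreasing mean similarity index).
#'
#' @param instance A \code{ts_instance}.
#' @param costs A \code{ts_costs}.
#' @param extended Use the extended model (dynamic birth cost; disables
#'   pruning, so every topology is visited)?
#' @param seed Integer seed for the sampling initialisation.
#' @param samples Random samples per tree count for the initial upper bound.
#' @param max_trees Optional cap on the number of trees explored.
#' @param prune Disable to force visiting every topology (used for
#'   self-consistency checks).
#' @param max_solutions Cap on retained co-optimal assignments per topology.
#' @param ancestral Optional precomputed exon-state matrix.
#' @return An object of class \code{ts_result}: list with \code{score},
#'   \code{solutions} (ranked records), \code{n_solutions} (count of
#'   minimum-cost solutions before the secondary filter), \code{stats}
#'   (per-tree-count data frame: generated, pruned, refined; when pruning is
#'   active, partial forests whose bound already exceeds the incumbent are
#'   cut during generation, so \code{generated} counts the topologies that
#'   survive that cut), \code{status} (\code{"ok"} or \code{"no_solution"})
#'   and the inputs used.
#' @export
infer_transcript_phylogenies <- function(instance, costs = ts_costs(),
                                         extended = FALSE, seed = 1,
                                         samples = 3, max_trees = NULL,
                                         prune = TRUE, max_solutions = 2000,
                                         ancestral = NULL) {
  stopifnot(inherits(instance, "ts_instance"))
  tree <- instance$tree
  if (is.null(ancestral))
    ancestral <- reconstruct_ancestral_exon_states(tree, leaf_exon_states(instance))
  Z <- zero_cost_mask(ancestral, tree)
  counts <- vapply(instance$transcripts, nrow, 1L)
  catalog <- shape_catalog(tree)
  need <- check_leaf_counts(catalog, counts)
  t_max <- if (is.null(max_trees)) sum(need) else min(max_trees, sum(need))
  t_range <- if (t_max >= max(need)) seq(max(need), t_max) else integer(0)
  use_prune <- prune && !extended
  incumbent <- if (use_prune)
    sample_initial_upper_bound(instance, costs, samples, seed,
                               catalog = catalog, ancestral = ancestral)
  else Inf
  # per-shape lower-bound weights: death cost plus the relaxed per-tree
  # Sankoff score (as if all transcripts were available); used both to cut
  # partial forests during generation and as the final per-topology bound
  lb_w <- NULL
  if (use_prune) {
    prof_cache <- new.env(parent = emptyenv())
    lb_w <- rep(0, length(catalog$node))
    for (sid in which(catalog$proper)) {
      lb_w[sid] <- costs$c_D * catalog$deaths[sid] +
        min_mp(shape_relaxed_profile(catalog, sid, instance, ancestral, Z,
                                     costs, prof_cache))
    }
  }
  stats <- list()
  hits <- list()   # list of (score, solutions records)
  best <- Inf
  for (t in t_range) {
    bound <- min(incumbent, best)
    if (use_prune && is.finite(bound) && costs$c_B * t > bound + 1e-9)
      break
    grp <- if (use_prune)
      topologies_of_size(catalog, need, t, weights = lb_w,
                         base_cost = costs$c_B * t, bound = bound)
    else topologies_of_size(catalog, need, t)
    if (!length(grp)) {
      stats[[length(stats) + 1L]] <- data.frame(
        n_trees = t, generated = 0L, pruned = 0L, refined = 0L)
      next
    }
    n_pruned <- 0L; n_refined <- 0L
    for (ix in seq_along(grp)) {
      topo <- grp[[ix]]
      if (use_prune) {
        lb <- costs$c_B * t + sum(lb_w[topo$ids])
        if (lb > min(incumbent, best) + 1e-9) { n_pruned <- n_pruned + 1L; next }
      }
      n_refined <- n_refined + 1L
      res <- tryCatch(
        assign_leaves(topo, instance, ancestral, costs,
                      max_solutions = max_solutions),
        error = function(e) {
          warning("topology skipped: ", conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(res) || !is.finite(res$S_F)) next
      ti <- instantiate_topology(topo)
      sols <- lapply(res$solutions, function(ch)
        build_solution(ti, res$states, ch, instance, ancestral, Z, costs))
      if (extended) {
        for (i in seq_along(sols)) {
          ext <- extended_birth_cost(sols[[i]], tree, costs)
          sols[[i]]$birth_costs <- ext$birth_costs
          sols[[i]]$S <- ext$S_extended
        }
      }
      for (s in sols) {
        if (!is.finite(s$S)) next
        if (s$S < best - 1e-9) { best <- s$S; hits <- list() }
        if (s$S < best + 1e-9) hits[[length(hits) + 1L]] <- s
      }
      incumbent <- min(incumbent, best)
    }
    stats[[length(stats) + 1L]] <- data.frame(
      n_trees = t, generated = length(grp), pruned = n_pruned,
      refined = n_refined)
  }
  stats <- do.call(rbind, stats)
  if (!length(hits) || !is.finite(best)) {
    return(structure(list(score = Inf, solutions = list(), n_solutions = 0L,
                          stats = stats, status = "no_solution",
                          costs = costs, ancestral = ancestral),
                     class = "ts_result"))
  }
  # drop duplicates (same labeled forest reached via symmetric states)
  keys <- vapply(hits, function(s) s$key, "")
  hits <- hits[!duplicated(keys)]
  n_min <- length(hits)
  # secondary filter: minimum number of evolutionary events, then rank by
  # decreasing mean similarity index (ties by forest key)
  n_gene_events <- nrow(gene_level_events(ancestral, tree))
  ev <- vapply(hits, function(s)
    s$n_changes + s$N_tree + s$N_death + n_gene_events, 0)
  hits <- hits[ev <= min(ev) + 1e-9]
  ord <- order(-vapply(hits, function(s) s$mean_similarity, 0),
               vapply(hits, function(s) s$key, ""))
  hits <- hits[ord]
  structure(list(score = best, solutions = hits, n_solutions = n_min,
                 stats = stats, status = "ok", costs = costs,
                 ancestral = ancestral),
            class = "ts_result")
}

#' @export
print.ts_result <- function(x, ...) {
  if (x$status == "no_solution") {
    cat("No transcript phylogeny with finite score could be found.\n")
    return(invisible(x))
  }
  cat("Minimum score S =", x$score, "with", x$n_solutions,
      "minimum-cost solution(s);", length(x$solutions),
      "after the minimum-event filter.\n")
  s <- x$solutions[[1]]
  cat("Best-ranked solution: N_tree =", s$N_tree, ", N_death =", s$N_death,
      ", S_F =", s$S_F, "\n")
  for (tr in s$tree_strings) cat("  ", tr, "\n")
  invisible(x)
}

#' Serialize an inference result to JSON
#'
#' @param res A \code{ts_result}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_results <- function(res, path) {
  sols <- lapply(res$solutions, function(s) {
    list(S = s$S, S_F = s$S_F, N_tree = s$N_tree, N_death = s$N_death,
         trees = s$tree_strings, similarity = s$similarity,
         ancestral_vectors = lapply(s$trees, function(nd) nd$vector),
         topology = s$topology_key)
  })
  out <- list(status = res$status,
              score = if (is.finite(res$score)) res$score else "Inf",
              n_solutions = res$n_solutions,
              costs = unclass(res$costs),
              solutions = sols,
              search_stats = res$stats)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
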