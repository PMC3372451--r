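# Synthetic instances with known ground truth, an independent brute-force
# oracle (direct forest enumeration + exhaustive leaf bijections), and the
# optimality benchmark.

#' Build a caterpillar gene tree
#'
#' A rooted binary tree in which one of the two children of every internal
#' node is a leaf; depth is maximal (\code{n_leaves - 1}) for the leaf count,
#' which makes caterpillars the hard case for the leaf-assignment heuristic.
#'
#' @param n_leaves Number of leaf genes (>= 2).
#' @param labels Optional leaf labels (default \code{g1..gn}).
#' @return A \code{gene_tree}.
#' @export
make_caterpillar <- function(n_leaves, labels = NULL) {
  if (!is.numeric(n_leaves) || n_leaves < 2 || n_leaves != round(n_leaves))
    stop("n_leaves must be an integer >= 2", call. = FALSE)
  if (is.null(labels)) labels <- paste0("g", seq_len(n_leaves))
  stopifnot(length(labels) == n_leaves)
  nwk <- paste0("(", labels[1], ",", labels[2], ")I1")
  if (n_leaves > 2) {
    for (i in 3:n_leaves)
      nwk <- paste0("(", nwk, ",", labels[i], ")I", i - 1L)
  }
  as_gene_tree(ape::read.tree(text = paste0(nwk, ";")))
}

#' Balanced gene tree
#'
#' @param n_leaves Number of leaves (>= 2); as balanced as possible.
#' @param labels Optional leaf labels.
#' @return A \code{gene_tree}.
#' @export
make_balanced <- function(n_leaves, labels = NULL) {
  if (is.null(labels)) labels <- paste0("g", seq_len(n_leaves))
  build <- function(lo, hi) {
    if (lo == hi) return(labels[lo])
    mid <- (lo + hi) %/% 2
    paste0("(", build(lo, mid), ",", build(mid + 1, hi), ")")
  }
  as_gene_tree(ape::read.tree(text = paste0(build(1, n_leaves), ";")))
}

#' Simulation configuration
#'
#' Per-edge event probabilities of the generative two-level process. The
#' defaults (0.05 per edge per exon or transcript) keep events sparse:
#' visible signal with occasional noise, the regime the reconstruction is
#' meant for. \code{n_T = NULL} draws the number of ancestral transcripts
#' uniformly from 1..4.
#'
#' @param n_E Exon columns present at the root (>= 1); as many again start
#'   absent and may be born along the tree.
#' @param n_T Ancestral transcripts at the root, or \code{NULL} for random.
#' @param p_exon_birth,p_exon_death Gene-level exon event probabilities.
#' @param p_gain,p_loss Transcript-level exon gain/loss probabilities (per
#'   transcript per alternative exon per edge).
#' @param p_t_death,p_t_birth Transcript death/birth probabilities (per
#'   transcript per edge).
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_E = 10, n_T = NULL, p_exon_birth = 0.05,
                       p_exon_death = 0.05, p_gain = 0.05, p_loss = 0.05,
                       p_t_death = 0.05, p_t_birth = 0.05) {
  p <- c(p_exon_birth, p_exon_death, p_gain, p_loss, p_t_death, p_t_birth)
  if (any(p < 0) || any(p > 1)) stop("probabilities must be in [0,1]", call. = FALSE)
  if (n_E < 1) stop("n_E must be >= 1", call. = FALSE)
  if (!is.null(n_T) && n_T < 1) stop("n_T must be >= 1", call. = FALSE)
  structure(list(n_E = as.integer(n_E), n_T = n_T,
                 p_exon_birth = p_exon_birth, p_exon_death = p_exon_death,
                 p_gain = p_gain, p_loss = p_loss,
                 p_t_death = p_t_death, p_t_birth = p_t_birth),
            class = "sim_config")
}

#' Simulate transcript evolution on a gene tree
#'
#' Starting from \code{n_T} ancestral transcripts over \code{n_E} root exons
#' (plus as many initially absent columns), exons are born and die along each
#' edge at the gene level; transcripts inherit from the parent gene, can die,
#' gain or lose currently-alternative exons, and new transcripts are born as
#' a copy of a random existing transcript with one random flip. A transcript
#' lineage never goes fully extinct at a node: if every transcript would die
#' on an edge, one survivor is kept (flagged in the truth record). All
#' randomness is governed by \code{seed}.
#'
#' @param tree A \code{gene_tree}.
#' @param config A \code{sim_config}.
#' @param seed Integer seed.
#' @return An object of class \code{ts_sim}: list with \code{instance} (a
#'   \code{ts_instance} of the observed leaf transcripts), and \code{truth}
#'   (true exon-state matrix, event counts \code{n_births}, \code{n_deaths},
#'   \code{n_changes}, \code{dollo_ok} flag, \code{resampled} flag).
#' @export
simulate_instance <- function(tree, config = sim_config(), seed = 1) {
  stopifnot(inherits(tree, "gene_tree"), inherits(config, "sim_config"))
  set.seed(seed)
  n <- length(tree$label)
  ncols <- 2L * config$n_E
  cols <- paste0("e", seq_len(ncols))
  n_T <- if (is.null(config$n_T)) sample(1:4, 1) else config$n_T

  states <- matrix(EXON_ABSENT, nrow = n, ncol = ncols,
                   dimnames = list(tree$label, cols))
  gains <- integer(ncols)
  root <- tree$root
  states[root, seq_len(config$n_E)] <-
    sample(c(EXON_ALTERNATIVE, EXON_CONSTITUTIVE), config$n_E, replace = TRUE)
  gains[seq_len(config$n_E)] <- 1L

  root_t <- matrix(0L, nrow = n_T, ncol = ncols)
  for (i in seq_len(n_T)) {
    root_t[i, states[root, ] == EXON_CONSTITUTIVE] <- 1L
    alt <- which(states[root, ] == EXON_ALTERNATIVE)
    root_t[i, alt] <- as.integer(stats::runif(length(alt)) < 0.5)
  }

  n_births <- n_T; n_deaths <- 0L; n_changes <- 0L; resampled <- FALSE
  tr_at <- vector("list", n)  # transcript matrices per node
  tr_at[[root]] <- root_t

  for (v in rev(tree$postorder)) {          # preorder: parents before children
    if (tree$is_leaf[v]) next
    for (ch in c(tree$left[v], tree$right[v])) {
      st <- states[v, ]
      tm <- tr_at[[v]]
      # gene level
      present <- which(st != EXON_ABSENT)
      die <- present[stats::runif(length(present)) < config$p_exon_death]
      if (length(die)) { st[die] <- EXON_ABSENT; tm[, die] <- 0L }
      absent <- which(st == EXON_ABSENT)
      born <- absent[stats::runif(length(absent)) < config$p_exon_birth]
      for (j in born) {
        st[j] <- sample(c(EXON_ALTERNATIVE, EXON_CONSTITUTIVE), 1)
        gains[j] <- gains[j] + 1L
        if (st[j] == EXON_CONSTITUTIVE) tm[, j] <- 1L
      }
      # transcript deaths (never all)
      dead <- which(stats::runif(nrow(tm)) < config$p_t_death)
      if (length(dead) == nrow(tm)) {
        keep <- sample(seq_len(nrow(tm)), 1)
        dead <- setdiff(dead, keep)
        resampled <- TRUE
      }
      if (length(dead)) { tm <- tm[-dead, , drop = FALSE]; n_deaths <- n_deaths + length(dead) }
      # transcript-level gains/losses on alternative exons
      alt <- which(st == EXON_ALTERNATIVE)
      for (i in seq_len(nrow(tm))) {
        for (j in alt) {
          if (tm[i, j] >= 1L) {
            if (stats::runif(1) < config$p_loss) { tm[i, j] <- 0L; n_changes <- n_changes + 1L }
          } else {
            if (stats::runif(1) < config$p_gain) { tm[i, j] <- 1L; n_changes <- n_changes + 1L }
          }
        }
        tm[i, st == EXON_CONSTITUTIVE] <- 1L
        tm[i, st == EXON_ABSENT] <- 0L
      }
      # transcript births: copy + one random flip (the flip is part of the
      # hidden birth relationship, not a charged change)
      nb <- stats::rbinom(1, nrow(tm), config$p_t_birth)
      for (b in seq_len(nb)) {
        src <- tm[sample(seq_len(nrow(tm)), 1), , drop = FALSE]
        if (length(alt)) {
          j <- if (length(alt) == 1) alt else sample(alt, 1)
          src[1, j] <- if (src[1, j] >= 1L) 0L else 1L
        }
        tm <- rbind(tm, src)
        n_births <- n_births + 1L
      }
      states[ch, ] <- st
      tr_at[[ch]] <- tm
    }
  }

  transcripts <- list()
  for (v in which(tree$is_leaf)) {
    tm <- tr_at[[v]]
    rownames(tm) <- paste0(tree$label[v], ".t", seq_len(nrow(tm)))
    colnames(tm) <- cols
    transcripts[[tree$label[v]]] <- tm
  }
  instance <- ts_instance(tree, transcripts, columns = cols)
  structure(list(
    instance = instance,
    truth = list(states = states, n_births = n_births, n_deaths = n_deaths,
                 n_changes = n_changes, dollo_ok = all(gains <= 1L),
                 resampled = resampled, n_T = n_T, seed = seed)),
    class = "ts_sim")
}

#' Write a simulated instance to files
#'
#' Same Newick + TSV formats as real inputs, plus a ground-truth JSON
#' sidecar.
#'
#' @param sim A \code{ts_sim}.
#' @param prefix Path prefix; writes \code{<prefix>.nwk}, \code{<prefix>.tsv}
#'   and \code{<prefix>.truth.json}.
#' @return Invisibly, the three paths.
#' @export
write_simulated_instance <- function(sim, prefix) {
  stopifnot(inherits(sim, "ts_sim"))
  paths <- c(paste0(prefix, ".nwk"), paste0(prefix, ".tsv"),
             paste0(prefix, ".truth.json"))
  write_instance(sim$instance, paths[1], paths[2])
  tr <- sim$truth
  tok <- apply(tr$states, c(1, 2), state_token)
  jsonlite::write_json(
    list(states = as.data.frame(tok), n_births = tr$n_births,
         n_deaths = tr$n_deaths, n_changes = tr$n_changes,
         dollo_ok = tr$dollo_ok, resampled = tr$resampled,
         n_T = tr$n_T, seed = tr$seed),
    paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# ---- independent brute-force oracle ---------------------------------------

#' Brute-force topology enumeration (oracle)
#'
#' Demand-driven construction, independent of
#' \code{\link{enumerate_topologies}}: repeatedly attach any proper shape
#' covering the first leaf gene whose transcript demand is unmet, then
#' filter by validity and deduplicate. Used as the reference enumerator in
#' tests and by \code{\link{brute_force_optimal}}.
#'
#' @param tree A \code{gene_tree} or \code{shape_catalog}.
#' @param leaf_counts Named integer vector of transcripts per leaf gene.
#' @param n_trees_exact Optional: keep only forests with exactly this many
#'   trees (the construction is also pruned accordingly).
#' @return A list of \code{ts_topology} (unordered, no duplicates).
#' @export
enumerate_topologies_bruteforce <- function(tree, leaf_counts,
                                            n_trees_exact = NULL) {
  cat <- if (inherits(tree, "shape_catalog")) tree else shape_catalog(tree)
  tree <- cat$tree
  need <- integer(length(tree$label))
  need[node_index(tree, names(leaf_counts))] <- as.integer(leaf_counts)
  ok <- which(cat$proper)
  lc <- do.call(rbind, cat$leafcover[ok])
  leaf_nodes <- which(tree$is_leaf)
  seen <- new.env(parent = emptyenv())
  out <- list()
  grow <- function(remaining, chosen) {
    unmet <- leaf_nodes[remaining[leaf_nodes] > 0L]
    if (!length(unmet)) {
      if (!is.null(n_trees_exact) && length(chosen) != n_trees_exact)
        return(invisible(NULL))
      key <- paste(sort(chosen), collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        tp <- topology(cat, ok[chosen])
        if (is_valid_topology(tp)) out[[length(out) + 1L]] <<- tp
      }
      return(invisible(NULL))
    }
    if (!is.null(n_trees_exact) && length(chosen) >= n_trees_exact)
      return(invisible(NULL))
    g <- unmet[1]
    for (i in seq_along(ok)) {
      if (lc[i, g] == 0L) next
      if (any(lc[i, ] > remaining)) next
      grow(remaining - lc[i, ], c(chosen, i))
    }
    invisible(NULL)
  }
  grow(need, integer(0))
  out
}

# plain recursive Sankoff on one shape for a fixed choice of transcript per
# covered leaf gene (pick: named vector gene label -> transcript row)
oracle_shape_profile <- function(cat, sid, pick, instance, ancestral, Z, c_E) {
  tree <- cat$tree
  v <- cat$node[sid]
  alphabet <- instance$alphabet
  A <- max(alphabet); ncols <- length(alphabet)
  if (tree$is_leaf[v]) {
    vec <- instance$transcripts[[tree$label[v]]][pick[[tree$label[v]]], ]
    m <- matrix(Inf, ncols, A + 1L)
    m[cbind(seq_len(ncols), vec + 1L)] <- 0
    return(m)
  }
  m <- matrix(0, ncols, A + 1L)
  for (cs in list(cat$left[sid], cat$right[sid])) {
    if (is.na(cs)) next
    cp <- oracle_shape_profile(cat, cs, pick, instance, ancestral, Z, c_E)
    cv <- cat$node[cs]
    add <- matrix(0, ncols, A + 1L)
    for (i in seq_len(ncols)) {
      for (u in 0:A) {
        best <- Inf
        for (x in 0:A) {
          tr <- if (Z[cv, i]) 0 else if (u == x) 0 else c_E
          val <- tr + cp[i, x + 1L]
          if (val < best) best <- val
        }
        add[i, u + 1L] <- best
      }
    }
    m <- m + add
  }
  for (u in seq_len(A)) m[alphabet < u, u + 1L] <- Inf
  absent <- ancestral[v, ] == EXON_ABSENT
  if (any(absent)) m[absent, -1L] <- Inf
  m
}

# exact optimum of one topology by exhausting every leaf bijection
oracle_topology_optimum <- function(topo, instance, ancestral, Z, costs,
                                    guard = 1e6) {
  cat <- topo$cat; tree <- cat$tree
  ids <- topo$ids
  counts <- vapply(instance$transcripts, nrow, 1L)
  # which leaf genes each tree covers
  covered <- lapply(ids, function(sid) {
    cv <- cat$cover[[sid]]
    tree$label[cv[tree$is_leaf[cv]]]
  })
  n_assign <- prod(factorial(counts))
  if (n_assign > guard)
    stop("assignment space too large for the brute-force oracle (",
         format(n_assign), " > ", format(guard), ")", call. = FALSE)
  # per tree: table of scores over choices of one transcript per covered gene
  tabs <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    genes <- covered[[k]]
    grid <- expand.grid(lapply(counts[genes], seq_len))
    colnames(grid) <- genes
    sc <- numeric(nrow(grid))
    for (r in seq_len(nrow(grid))) {
      pick <- as.list(grid[r, , drop = FALSE])
      prof <- oracle_shape_profile(cat, ids[k], pick, instance, ancestral, Z,
                                   costs$c_E)
      sc[r] <- sum(apply(prof, 1, min))
    }
    tabs[[k]] <- list(genes = genes, grid = as.matrix(grid), score = sc)
  }
  # slots per leaf gene: ordered list of (tree index) needing one transcript
  leaves <- names(counts)
  slot_trees <- lapply(leaves, function(g)
    which(vapply(covered, function(cg) g %in% cg, TRUE)))
  names(slot_trees) <- leaves
  perms <- lapply(leaves, function(g) injections(seq_len(counts[[g]]), counts[[g]]))
  names(perms) <- leaves
  # assignment: for each gene, perm[p] gives transcript row for the p-th slot
  # (slot p belongs to tree slot_trees[[g]][p])
  best <- Inf
  pick_rows <- function(gi, rows_by_tree) {
    if (gi > length(leaves)) {
      tot <- 0
      for (k in seq_along(ids)) {
        tb <- tabs[[k]]
        if (!length(tb$genes)) next
        row <- vapply(tb$genes, function(g) rows_by_tree[[k]][[g]], 0L)
        hit <- which(colSums(abs(t(tb$grid) - row)) == 0)[1]
        tot <- tot + tb$score[hit]
        if (tot >= best) break
      }
      best <<- min(best, tot)
      return(invisible(NULL))
    }
    g <- leaves[gi]
    for (perm in perms[[g]]) {
      rbt <- rows_by_tree
      for (p in seq_along(perm)) {
        k <- slot_trees[[g]][p]
        rbt[[k]][[g]] <- perm[p]
      }
      pick_rows(gi + 1L, rbt)
    }
    invisible(NULL)
  }
  rows_by_tree <- rep(list(list()), length(ids))
  pick_rows(1L, rows_by_tree)
  list(S_F = best,
       S = score_solution(n_trees(topo), n_deaths(topo), best, costs))
}

#' Exact optimum by exhaustive enumeration
#'
#' Enumerates topologies with the independent demand-driven constructor (or
#' uses the supplied ones) and, per topology, every possible assignment of
#' observed transcripts to leaf slots, scoring each tree with a plain
#' Sankoff pass. Exact but exponential; guarded by the assignment-space
#' bound.
#'
#' @param instance A \code{ts_instance}.
#' @param costs A \code{ts_costs}.
#' @param topologies Optional list of \code{ts_topology}; default: all.
#' @param ancestral Optional exon-state matrix.
#' @param guard Refuse when (number of topologies) x (bijections) exceeds
#'   this bound.
#' @return List with \code{score} (global optimum, \code{Inf} if no valid
#'   topology), and \code{per_topology} (data frame: key, n_tree, n_death,
#'   S_F, S).
#' @export
brute_force_optimal <- function(instance, costs = ts_costs(), topologies = NULL,
                                ancestral = NULL, guard = 1e6) {
  stopifnot(inherits(instance, "ts_instance"))
  tree <- instance$tree
  counts <- vapply(instance$transcripts, nrow, 1L)
  if (is.null(ancestral))
    ancestral <- reconstruct_ancestral_exon_states(tree, leaf_exon_states(instance))
  Z <- zero_cost_mask(ancestral, tree)
  score_set <- function(topos, rows, best) {
    n_assign <- length(topos) * prod(factorial(counts))
    if (n_assign > guard)
      stop("assignment space too large for the brute-force oracle (",
           format(n_assign), " > ", format(guard), ")", call. = FALSE)
    for (tp in topos) {
      opt <- oracle_topology_optimum(tp, instance, ancestral, Z, costs,
                                     guard = guard)
      rows[[length(rows) + 1L]] <- data.frame(
        key = canonical_key(tp), n_tree = n_trees(tp), n_death = n_deaths(tp),
        S_F = opt$S_F, S = opt$S, stringsAsFactors = FALSE)
      best <- min(best, opt$S)
    }
    list(rows = rows, best = best)
  }
  rows <- list(); best <- Inf
  if (!is.null(topologies)) {
    res <- score_set(topologies, rows, best)
    rows <- res$rows; best <- res$best
  } else {
    # enumerate by tree count; once c_B * t alone exceeds the best score so
    # far, no larger forest can win (deaths and S_F are non-negative)
    cat <- shape_catalog(tree)
    for (t in seq(max(counts), sum(counts))) {
      if (is.finite(best) && costs$c_B * t > best + 1e-9) break
      topos <- enumerate_topologies_bruteforce(cat, counts, n_trees_exact = t)
      res <- score_set(topos, rows, best)
      rows <- res$rows; best <- res$best
    }
  }
  if (!length(rows)) {
    return(list(score = Inf,
                per_topology = data.frame(key = character(0), n_tree = integer(0),
                                          n_death = integer(0), S_F = numeric(0),
                                          S = numeric(0))))
  }
  list(score = best, per_topology = do.call(rbind, rows))
}

# ---- benchmark -------------------------------------------------------------

#' Size of the topology space
#'
#' Counts, by dynamic programming, the multisets of proper tree shapes whose
#' leaf coverage equals the observed transcript counts -- the size of the
#' topology space before the connectivity filter. Exact and fast even when
#' enumeration is hopeless.
#'
#' @param tree A \code{gene_tree} or \code{shape_catalog}.
#' @param leaf_counts Named integer vector of transcripts per leaf gene.
#' @return Named numeric vector: count of forests per number of trees
#'   (names are the tree counts).
#' @export
count_topology_space <- function(tree, leaf_counts) {
  cat <- if (inherits(tree, "shape_catalog")) tree else shape_catalog(tree)
  need <- check_leaf_counts(cat, leaf_counts)
  leaf_nodes <- which(cat$tree$is_leaf)
  k <- need[leaf_nodes]
  radix <- cumprod(c(1, k[-length(k)] + 1))
  n_states <- prod(k + 1)
  digits <- as.matrix(expand.grid(lapply(k, function(m) 0:m)))
  t_max <- sum(k)
  ok <- which(cat$proper)
  # ways[t+1, state]: multisets of t shapes among those processed so far
  ways <- matrix(0, nrow = t_max + 1L, ncol = n_states)
  ways[1L, 1L] <- 1
  for (i in ok) {
    cov <- cat$leafcover[[i]][leaf_nodes]
    valid <- which(colSums(t(digits) >= cov) == length(k))
    src <- valid - as.integer(sum(cov * radix))
    for (t in seq_len(t_max)) {
      ways[t + 1L, valid] <- ways[t + 1L, valid] + ways[t, src]
    }
  }
  full <- n_states  # state with all demands met
  counts <- ways[-1L, full]
  names(counts) <- seq_len(t_max)
  counts[counts > 0]
}

#' Benchmark the leaf assignment against the exhaustive oracle
#'
#' For each (leaf count, ancestral transcript count) cell, simulates
#' \code{n_runs} caterpillar instances, and for every topology of each
#' instance compares the leaf-assignment score with the per-topology
#' brute-force optimum. Reports the optimality percentage (share of
#' topologies where the two scores agree), the mean and sd of the score
#' difference, the average topology-space size, and the fraction of
#' topologies that survive lower-bound pruning in a full search.
#'
#' @param leaf_sizes Integer vector of caterpillar leaf counts.
#' @param transcripts Integer vector of ancestral transcript counts.
#' @param n_runs Runs per cell.
#' @param costs A \code{ts_costs}.
#' @param config A \code{sim_config} (its \code{n_T} is overridden per cell).
#' @param seed Integer base seed.
#' @param guard Per-instance bound on the bijection space
#'   (\code{prod(k_g!)}); instances exceeding it are refused (error) unless
#'   \code{skip_oversize} is \code{TRUE}.
#' @param skip_oversize Skip (rather than refuse) oversize instances.
#' @param max_eval Cap on the number of topologies compared per run (taken
#'   in deterministic tree-count/canonical-key order); the topology space
#'   grows faster than exponentially, so exhausting it is only feasible for
#'   the smallest instances.
#' @return Data frame with one row per cell: \code{leaves},
#'   \code{transcripts}, \code{runs}, \code{optimality_pct},
#'   \code{mean_diff}, \code{sd_diff}, \code{topologies_total} (average
#'   topology-space size from \code{\link{count_topology_space}}),
#'   \code{topologies_refined_pct} (average share of that space the pruned
#'   search actually passed to the leaf assignment).
#' @export
benchmark_optimality <- function(leaf_sizes, transcripts, n_runs = 10,
                                 costs = ts_costs(), config = sim_config(),
                                 seed = 1, guard = 1e6, skip_oversize = FALSE,
                                 max_eval = 150) {
  empty <- data.frame(leaves = integer(0), transcripts = integer(0),
                      runs = integer(0), optimality_pct = numeric(0),
                      mean_diff = numeric(0), sd_diff = numeric(0),
                      topologies_total = numeric(0),
                      topologies_refined_pct = numeric(0))
  if (n_runs < 1) return(empty)
  out <- list()
  for (L in leaf_sizes) for (k in transcripts) {
    cfg <- config; cfg$n_T <- as.integer(k)
    diffs <- c(); agree <- c(); topo_n <- c(); refined <- c()
    runs_done <- 0L
    for (r in seq_len(n_runs)) {
      s <- (seed + 7919L * r + 104729L * L + 1299709L * k) %% 2147483647L
      tree <- make_caterpillar(L)
      sim <- simulate_instance(tree, cfg, seed = s)
      inst <- sim$instance
      counts <- vapply(inst$transcripts, nrow, 1L)
      if (prod(factorial(counts)) > guard) {
        if (skip_oversize) next
        stop("instance exceeds the oracle guard (leaves=", L, ", run=", r,
             "); reduce sizes", call. = FALSE)
      }
      ancestral <- reconstruct_ancestral_exon_states(tree, leaf_exon_states(inst))
      Z <- zero_cost_mask(ancestral, tree)
      cat <- shape_catalog(tree)
      need <- check_leaf_counts(cat, counts)
      res <- infer_transcript_phylogenies(inst, costs, seed = s,
                                          max_solutions = 50)
      space <- sum(count_topology_space(cat, counts))
      n_eval <- 0L; n_seen <- 0L
      for (t in seq(max(need), sum(need))) {
        grp <- topologies_of_size(cat, need, t)
        n_seen <- n_seen + length(grp)
        for (tp in grp) {
          if (n_eval >= max_eval) break
          dp <- tryCatch(assign_leaves(tp, inst, ancestral, costs,
                                       max_solutions = 1),
                         error = function(e) NULL)
          if (is.null(dp)) next
          opt <- oracle_topology_optimum(tp, inst, ancestral, Z, costs, guard)
          d <- dp$S_F - opt$S_F
          if (!is.finite(dp$S_F) && !is.finite(opt$S_F)) d <- 0
          diffs <- c(diffs, d)
          agree <- c(agree, abs(d) < 1e-9)
          n_eval <- n_eval + 1L
        }
        if (n_seen >= 2L * max_eval) break
      }
      topo_n <- c(topo_n, space)
      # share of the whole topology space the search actually refined
      refined <- c(refined, sum(res$stats$refined) / space)
      runs_done <- runs_done + 1L
    }
    out[[length(out) + 1L]] <- data.frame(
      leaves = L, transcripts = k, runs = runs_done,
      optimality_pct = 100 * mean(agree),
      mean_diff = mean(diffs), sd_diff = stats::sd(diffs),
      topologies_total = mean(topo_n),
      topologies_refined_pct = 100 * mean(refined))
  }
  do.call(rbind, out)
}
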