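# Ancestral gene exon states: Sankoff small parsimony with unit transition
# costs, constrained so that no exon column is gained more than once (Dollo).

#' Infer leaf exon states from observed transcripts
#'
#' A column is constitutive at a leaf gene iff every transcript of that gene
#' includes it (value >= 1), alternative iff some but not all include it, and
#' absent iff none does. Leaf states are inferred purely from transcripts;
#' present-but-never-spliced-in exons cannot be distinguished from absent
#' ones.
#'
#' @param instance A \code{ts_instance}.
#' @return Integer matrix (leaf genes x exon columns) with values 0 (absent),
#'   1 (alternative), 2 (constitutive); rownames are leaf gene labels.
#' @export
leaf_exon_states <- function(instance) {
  stopifnot(inherits(instance, "ts_instance"))
  leaves <- names(instance$transcripts)
  out <- matrix(EXON_ABSENT, nrow = length(leaves), ncol = length(instance$columns),
                dimnames = list(leaves, instance$columns))
  for (g in leaves) {
    m <- instance$transcripts[[g]]
    if (nrow(m) < 1) stop("leaf gene ", g, " has zero transcripts", call. = FALSE)
    inc <- m >= 1L
    frac <- colMeans(inc)
    out[g, ] <- ifelse(frac == 1, EXON_CONSTITUTIVE,
                       ifelse(frac > 0, EXON_ALTERNATIVE, EXON_ABSENT))
  }
  storage.mode(out) <- "integer"
  out
}

# Minimum number of unit-cost transitions for one column under the Dollo
# constraint, together with one (or all) optimal labelings.
#
# Implementation: a gain (absent -> present) can happen on at most one edge,
# or the root itself can start in a present state. For each candidate gain
# node v (the clade born present), states outside the clade are absent and a
# constrained Sankoff DP runs inside the clade where absent -> present
# transitions are forbidden. The minimum over candidates is the exact
# Dollo-constrained parsimony. Plain Sankoff co-optimal labelings are tried
# first; when one of them already satisfies Dollo it is necessarily optimal
# (the unconstrained optimum is a lower bound for the constrained one).
dollo_column <- function(tree, leaf_state, keep_all = FALSE) {
  n <- length(tree$label)
  INF <- Inf
  leaf_idx <- which(tree$is_leaf)

  if (all(leaf_state[leaf_idx] == EXON_ABSENT)) {
    lab <- rep(EXON_ABSENT, n)
    return(list(cost = 0, labeling = lab,
                all = if (keep_all) list(lab) else NULL))
  }

  # constrained Sankoff inside the clade of v: cost[v, s] over s in 0:2 with
  # transitions from 0 to {1,2} forbidden (gain already spent at the clade root)
  cost <- matrix(INF, nrow = n, ncol = 3)
  present_leaves <- leaf_idx[leaf_state[leaf_idx] != EXON_ABSENT]
  for (v in tree$postorder) {
    if (tree$is_leaf[v]) {
      cost[v, leaf_state[v] + 1L] <- 0
    } else {
      for (s in 0:2) {
        tot <- 0
        for (ch in c(tree$left[v], tree$right[v])) {
          best <- INF
          for (x in 0:2) {
            if (s == EXON_ABSENT && x != EXON_ABSENT) next  # no second gain
            tr <- if (s == x) 0 else 1
            best <- min(best, tr + cost[ch, x + 1L])
          }
          tot <- tot + best
        }
        cost[v, s + 1L] <- tot
      }
    }
  }

  # candidate clade roots: ancestors of present leaves (incl. the leaves)
  mrca_path <- unique(unlist(lapply(present_leaves,
                                    function(v) c(v, node_ancestors(tree, v)))))
  best_cost <- INF
  cands <- list()
  for (v in sort(mrca_path)) {
    for (s in c(EXON_ALTERNATIVE, EXON_CONSTITUTIVE)) {
      inside <- cost[v, s + 1L]
      if (!is.finite(inside)) next
      gain <- if (is.na(tree$parent[v])) 0 else 1
      # leaves outside the clade must be absent
      outside_ok <- all(vapply(leaf_idx, function(l)
        leaf_state[l] == EXON_ABSENT || is_descendant(tree, l, v), TRUE))
      if (!outside_ok) next
      tot <- gain + inside
      if (tot < best_cost - 1e-9) { best_cost <- tot; cands <- list() }
      if (tot < best_cost + 1e-9) cands[[length(cands) + 1L]] <- c(v, s)
    }
  }

  labelings <- list()
  for (cs in cands) {
    v <- cs[1]; s <- cs[2]
    labs <- dollo_backtrack(tree, cost, v, s, all = keep_all)
    for (lab in labs) {
      labelings[[length(labelings) + 1L]] <- lab
      if (!keep_all && length(labelings)) break
    }
    if (!keep_all && length(labelings)) break
  }
  # deterministic default: lexicographic over node labelings
  if (keep_all && length(labelings) > 1) {
    keys <- vapply(labelings, paste, "", collapse = "")
    labelings <- labelings[!duplicated(keys)]
    labelings <- labelings[order(vapply(labelings, paste, "", collapse = ""))]
  }
  list(cost = best_cost, labeling = labelings[[1]],
       all = if (keep_all) labelings else NULL)
}

is_descendant <- function(tree, v, anc) {
  if (v == anc) return(TRUE)
  anc %in% node_ancestors(tree, v)
}

# backtrack labelings given gain node v in state s; outside clade all absent
dollo_backtrack <- function(tree, cost, v, s, all = FALSE) {
  n <- length(tree$label)
  base <- rep(EXON_ABSENT, n)
  partials <- list(list(lab = base, todo = list(c(v, s))))
  done <- list()
  while (length(partials)) {
    p <- partials[[1]]; partials <- partials[-1]
    if (!length(p$todo)) { done[[length(done) + 1L]] <- p$lab; if (!all) break; next }
    node_s <- p$todo[[1]]; p$todo <- p$todo[-1]
    v0 <- node_s[1]; s0 <- node_s[2]
    p$lab[v0] <- s0
    if (tree$is_leaf[v0]) { partials[[length(partials) + 1L]] <- p; next }
    ch_opts <- list()
    for (ch in c(tree$left[v0], tree$right[v0])) {
      best <- Inf; opts <- integer(0)
      for (x in 0:2) {
        if (s0 == EXON_ABSENT && x != EXON_ABSENT) next
        val <- (if (s0 == x) 0 else 1) + cost[ch, x + 1L]
        if (val < best - 1e-9) { best <- val; opts <- x }
        else if (val < best + 1e-9) opts <- c(opts, x)
      }
      if (!all) opts <- opts[1]
      ch_opts[[length(ch_opts) + 1L]] <- list(ch = ch, opts = opts)
    }
    for (x1 in ch_opts[[1]]$opts) for (x2 in ch_opts[[2]]$opts) {
      q <- p
      q$todo <- c(q$todo, list(c(ch_opts[[1]]$ch, x1), c(ch_opts[[2]]$ch, x2)))
      partials[[length(partials) + 1L]] <- q
    }
    if (length(partials) > 5000) break  # cap enumeration of co-optima
  }
  done
}

#' Reconstruct ancestral gene exon states
#'
#' Runs Sankoff's small-parsimony dynamic program per exon column with unit
#' cost between any two distinct states, constrained so that each column is
#' gained (absent to present) on at most one edge of the gene tree (Dollo
#' parsimony). The root may take any Dollo-consistent state. When several
#' labelings are co-optimal, all are retrievable via the \code{"alternatives"}
#' attribute; the returned default is the first in a deterministic order
#' (lexicographic over node states, 0 < 1 < 2).
#'
#' @param tree A \code{gene_tree}.
#' @param leaf_states Integer matrix as returned by
#'   \code{\link{leaf_exon_states}}.
#' @param keep_all Keep all co-optimal labelings per column (attribute
#'   \code{"alternatives"}: a list, one entry per column)?
#' @return Integer matrix (all nodes x columns) of states 0/1/2, with
#'   attribute \code{"cost"} (per-column minimum transition count).
#' @export
reconstruct_ancestral_exon_states <- function(tree, leaf_states, keep_all = FALSE) {
  stopifnot(inherits(tree, "gene_tree"))
  leaves <- tree$label[tree$is_leaf]
  if (!all(leaves %in% rownames(leaf_states)))
    stop("leaf_states must have one row per leaf gene", call. = FALSE)
  n <- length(tree$label)
  ncols <- ncol(leaf_states)
  out <- matrix(EXON_ABSENT, nrow = n, ncol = ncols,
                dimnames = list(tree$label, colnames(leaf_states)))
  costs <- numeric(ncols)
  alts <- vector("list", ncols)
  for (j in seq_len(ncols)) {
    ls <- rep(NA_integer_, n)
    ls[match(leaves, tree$label)] <- leaf_states[leaves, j]
    res <- dollo_column(tree, ls, keep_all = keep_all)
    out[, j] <- res$labeling
    costs[j] <- res$cost
    if (keep_all) alts[[j]] <- res$all
  }
  storage.mode(out) <- "integer"
  attr(out, "cost") <- costs
  if (keep_all) attr(out, "alternatives") <- alts
  out
}

#' Gene-level exon events along the tree
#'
#' Compares parent and child states per column on every edge and classifies
#' the change: \code{gain_constitutive} (absent to constitutive: no
#' transcript had the exon and all will have it), \code{gain_alternative},
#' \code{loss} (present to absent), or \code{status_switch} (alternative to
#' constitutive or back). Constitutive gains and losses make the
#' corresponding transcript-level change free in the leaf assignment.
#'
#' @param matrix Full exon-state matrix (nodes x columns) as returned by
#'   \code{\link{reconstruct_ancestral_exon_states}}.
#' @param tree The \code{gene_tree}.
#' @return A data frame with columns \code{child} (label of the child end of
#'   the edge), \code{column}, \code{event}.
#' @export
gene_level_events <- function(matrix, tree) {
  stopifnot(inherits(tree, "gene_tree"))
  check_dollo(matrix, tree)
  rows <- list()
  for (v in seq_along(tree$label)) {
    p <- tree$parent[v]
    if (is.na(p)) next
    for (j in seq_len(ncol(matrix))) {
      a <- matrix[p, j]; b <- matrix[v, j]
      if (a == b) next
      ev <- if (a == EXON_ABSENT && b == EXON_CONSTITUTIVE) "gain_constitutive"
      else if (a == EXON_ABSENT && b == EXON_ALTERNATIVE) "gain_alternative"
      else if (b == EXON_ABSENT) "loss"
      else "status_switch"
      rows[[length(rows) + 1L]] <- data.frame(
        child = tree$label[v], column = colnames(matrix)[j], event = ev,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(child = character(0), column = character(0),
                      event = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# error if a column is gained on more than one edge (or at the root plus an edge)
check_dollo <- function(matrix, tree) {
  for (j in seq_len(ncol(matrix))) {
    gains <- 0L
    if (matrix[tree$root, j] != EXON_ABSENT) gains <- gains + 1L
    for (v in seq_along(tree$label)) {
      p <- tree$parent[v]
      if (is.na(p)) next
      if (matrix[p, j] == EXON_ABSENT && matrix[v, j] != EXON_ABSENT)
        gains <- gains + 1L
    }
    if (gains > 1L)
      stop("exon-state matrix violates the Dollo property in column ",
           colnames(matrix)[j], call. = FALSE)
  }
  invisible(TRUE)
}

# zero-cost mask: Z[child_node, column] TRUE when the edge parent->child carries
# a constitutive gain or a loss of that column
zero_cost_mask <- function(matrix, tree, events = NULL) {
  if (is.null(events)) events <- gene_level_events(matrix, tree)
  Z <- matrix(FALSE, nrow = nrow(matrix), ncol = ncol(matrix),
              dimnames = dimnames(matrix))
  keep <- events$event %in% c("gain_constitutive", "loss")
  if (any(keep)) {
    ev <- events[keep, , drop = FALSE]
    Z[cbind(match(ev$child, rownames(Z)), match(ev$column, colnames(Z)))] <- TRUE
  }
  Z
}

#' Dump a reconstructed exon-state matrix to TSV
#'
#' States are written as the tokens \code{0} (absent), \code{1A}
#' (alternative) and \code{1C} (constitutive).
#'
#' @param matrix State matrix (nodes x columns).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_exon_state_matrix <- function(matrix, path) {
  tok <- apply(matrix, c(1, 2), state_token)
  tab <- data.frame(gene = rownames(matrix), tok, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
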