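# Transcript-forest topologies. A topology is a forest of transcript trees
# whose leaves are not yet assigned; each tree is a subtree of the gene tree
# (each gene hosts at most one slot per tree). A topology is represented as a
# multiset of "shapes" from a per-instance catalog; a shape is a gene-subtree:
# a root gene plus, at every internal gene it covers, a continuation into the
# left child, the right child, or both. A shape node with no continuation at
# an internal gene ("bare") can arise from edge removal but is excluded from
# enumeration, since such a slot only adds a birth and two deaths.

#' Build the shape catalog for a gene tree
#'
#' Enumerates every subtree shape rooted at every gene node, including
#' degenerate shapes whose tips lie at internal genes (flagged
#' \code{proper = FALSE}). Shapes are shared by all topology operations.
#'
#' @param tree A \code{gene_tree}.
#' @param max_shapes Guard on catalog size.
#' @return An object of class \code{shape_catalog}.
#' @export
shape_catalog <- function(tree, max_shapes = 100000) {
  n <- length(tree$label)
  node <- integer(0); left <- integer(0); right <- integer(0)
  key <- character(0); proper <- logical(0); deaths <- integer(0)
  cover <- list(); leafcover <- list()
  by_node <- vector("list", n)
  lookup <- new.env(parent = emptyenv())

  add_shape <- function(v, l, r) {
    if (tree$is_leaf[v]) {
      k <- tree$label[v]
    } else {
      k <- paste0(tree$label[v], "(",
                  if (is.na(l)) "-" else key[l], ",",
                  if (is.na(r)) "-" else key[r], ")")
    }
    id <- length(node) + 1L
    if (id > max_shapes) stop("shape catalog exceeds max_shapes", call. = FALSE)
    node[id] <<- v; left[id] <<- l; right[id] <<- r; key[id] <<- k
    cv <- v
    pr <- TRUE; dt <- 0L
    if (!tree$is_leaf[v]) {
      if (is.na(l) && is.na(r)) { pr <- FALSE; dt <- 2L }
      else {
        if (is.na(l)) dt <- dt + 1L else { cv <- c(cv, cover[[l]]); pr <- pr && proper[l]; dt <- dt + deaths[l] }
        if (is.na(r)) dt <- dt + 1L else { cv <- c(cv, cover[[r]]); pr <- pr && proper[r]; dt <- dt + deaths[r] }
      }
    }
    cover[[id]] <<- cv
    lc <- integer(n); lc[cv[tree$is_leaf[cv]]] <- 1L
    leafcover[[id]] <<- lc
    proper[id] <<- pr; deaths[id] <<- dt
    by_node[[v]] <<- c(by_node[[v]], id)
    assign(k, id, envir = lookup)
    id
  }

  for (v in tree$postorder) {
    if (tree$is_leaf[v]) {
      add_shape(v, NA_integer_, NA_integer_)
    } else {
      ls <- c(NA_integer_, by_node[[tree$left[v]]])
      rs <- c(NA_integer_, by_node[[tree$right[v]]])
      for (l in ls) for (r in rs) add_shape(v, l, r)
    }
  }
  structure(list(tree = tree, node = node, left = left, right = right,
                 key = key, proper = proper, deaths = deaths,
                 cover = cover, leafcover = leafcover,
                 by_node = by_node, lookup = lookup),
            class = "shape_catalog")
}

shape_id_of <- function(cat, v, l, r) {
  if (cat$tree$is_leaf[v]) return(get(cat$tree$label[v], envir = cat$lookup))
  k <- paste0(cat$tree$label[v], "(",
              if (is.na(l)) "-" else cat$key[l], ",",
              if (is.na(r)) "-" else cat$key[r], ")")
  get(k, envir = cat$lookup)
}

#' Construct a topology from shape ids or shape strings
#'
#' Shape strings use the same syntax as shape keys: a leaf gene is its label,
#' an internal gene is \code{label(left,right)} with \code{-} for a side on
#' which the transcript lineage dies. Example: \code{"A(B(D,-),C(F,-))"}.
#'
#' @param cat A \code{shape_catalog} (or a \code{gene_tree}, from which one
#'   is built).
#' @param shapes Integer vector of shape ids, or character vector of shape
#'   strings.
#' @return An object of class \code{ts_topology}.
#' @export
topology <- function(cat, shapes) {
  if (inherits(cat, "gene_tree")) cat <- shape_catalog(cat)
  stopifnot(inherits(cat, "shape_catalog"))
  if (is.character(shapes)) {
    shapes <- vapply(shapes, function(s) {
      s <- gsub("[[:space:]]", "", s)
      if (!exists(s, envir = cat$lookup))
        stop("unknown shape: ", s, call. = FALSE)
      get(s, envir = cat$lookup)
    }, 1L, USE.NAMES = FALSE)
  }
  shapes <- as.integer(shapes)
  if (any(is.na(shapes)) || any(shapes < 1) || any(shapes > length(cat$node)))
    stop("invalid shape id", call. = FALSE)
  structure(list(cat = cat, ids = sort(shapes)), class = "ts_topology")
}

#' Number of trees of a topology
#' @param topo A \code{ts_topology}.
#' @return Integer count of transcript trees (= transcript births).
#' @export
n_trees <- function(topo) length(topo$ids)

#' Number of death events of a topology
#' @param topo A \code{ts_topology}.
#' @return Integer: for every slot at an internal gene, each child gene in
#'   which it has no child slot counts one death.
#' @export
n_deaths <- function(topo) sum(topo$cat$deaths[topo$ids])

#' Canonical key of a topology
#'
#' Equal keys iff the topologies are isomorphic under permuting slots within
#' a gene, i.e. iff they are the same multiset of tree shapes.
#'
#' @param topo A \code{ts_topology}.
#' @return A character scalar.
#' @export
canonical_key <- function(topo) {
  paste(sort(topo$cat$key[topo$ids]), collapse = "|")
}

#' @export
print.ts_topology <- function(x, ...) {
  cat("Topology:", n_trees(x), "tree(s),", n_deaths(x), "death(s)\n")
  for (k in sort(x$cat$key[x$ids])) cat("  ", k, "\n")
  invisible(x)
}

# per-gene slot counts implied by the multiset
slot_counts <- function(topo) {
  n <- length(topo$cat$tree$label)
  cnt <- integer(n)
  for (id in topo$ids) {
    cv <- topo$cat$cover[[id]]
    cnt[cv] <- cnt[cv] + 1L
  }
  cnt
}

#' Structural validity of a topology
#'
#' A topology is valid iff every gene hosts at least one slot and the graph
#' on genes -- with an edge between parent and child genes whenever at least
#' one slot link spans that gene-tree edge -- is connected.
#'
#' @param topo A \code{ts_topology}.
#' @return Logical scalar.
#' @export
is_valid_topology <- function(topo) {
  tree <- topo$cat$tree
  n <- length(tree$label)
  cnt <- slot_counts(topo)
  if (any(cnt == 0L)) return(FALSE)
  # covered gene-tree edges (identified by child node)
  covered <- rep(FALSE, n)
  for (id in topo$ids) {
    cv <- topo$cat$cover[[id]]
    if (length(cv) > 1) covered[setdiff(cv, cat_root_node(topo$cat, id))] <- TRUE
  }
  # connectivity on genes through covered edges
  seen <- rep(FALSE, n)
  stack <- tree$root; seen[tree$root] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (ch in c(tree$left[v], tree$right[v])) {
      if (!is.na(ch) && covered[ch] && !seen[ch]) { seen[ch] <- TRUE; stack <- c(stack, ch) }
    }
    p <- tree$parent[v]
    if (!is.na(p) && covered[v] && !seen[p]) { seen[p] <- TRUE; stack <- c(stack, p) }
  }
  all(seen)
}

cat_root_node <- function(cat, id) cat$node[id]

# does the topology's leaf slot count match the observed transcript counts?
matches_leaf_counts <- function(topo, leaf_counts) {
  tree <- topo$cat$tree
  cnt <- slot_counts(topo)
  idx <- node_index(tree, names(leaf_counts))
  all(cnt[idx] == as.integer(leaf_counts)) &&
    all(cnt[setdiff(which(tree$is_leaf), idx)] == 0L)
}

# ---- edit operations -------------------------------------------------------

# find, within shape sid, the shape node whose child covers gene c; returns
# list(new = pruned shape id, detached = subshape id) or NULL
shape_cut <- function(cat, sid, c) {
  l <- cat$left[sid]; r <- cat$right[sid]
  if (!is.na(l)) {
    if (cat$node[l] == c)
      return(list(new = shape_id_of(cat, cat$node[sid], NA_integer_, r), detached = l))
    res <- shape_cut(cat, l, c)
    if (!is.null(res))
      return(list(new = shape_id_of(cat, cat$node[sid], res$new, r), detached = res$detached))
  }
  if (!is.na(r)) {
    if (cat$node[r] == c)
      return(list(new = shape_id_of(cat, cat$node[sid], l, NA_integer_), detached = r))
    res <- shape_cut(cat, r, c)
    if (!is.null(res))
      return(list(new = shape_id_of(cat, cat$node[sid], l, res$new), detached = res$detached))
  }
  NULL
}

# replace, within shape sid, the subshape rooted at gene c by newsub
shape_graft <- function(cat, sid, c, newsub) {
  l <- cat$left[sid]; r <- cat$right[sid]
  if (!is.na(l)) {
    if (cat$node[l] == c) return(shape_id_of(cat, cat$node[sid], newsub, r))
    res <- shape_graft(cat, l, c, newsub)
    if (!is.na(res)) return(shape_id_of(cat, cat$node[sid], res, r))
  }
  if (!is.na(r)) {
    if (cat$node[r] == c) return(shape_id_of(cat, cat$node[sid], l, newsub))
    res <- shape_graft(cat, r, c, newsub)
    if (!is.na(res)) return(shape_id_of(cat, cat$node[sid], l, res))
  }
  NA_integer_
}

#' Remove an edge from a topology
#'
#' Disconnects the slot link spanning the gene-tree edge whose child end is
#' gene \code{child} within the \code{tree_index}-th tree (in canonical-key
#' order). The child slot becomes the root of a new tree (a birth) and the
#' parent slot gains a death on that side; the number of trees increases by
#' exactly one.
#'
#' @param topo A \code{ts_topology}.
#' @param tree_index Which tree of the forest (1-based, canonical order).
#' @param child Label of the gene at the child end of the link.
#' @return The new \code{ts_topology}.
#' @export
remove_edge <- function(topo, tree_index, child) {
  ids <- topo$ids[order(topo$cat$key[topo$ids])]
  if (tree_index < 1 || tree_index > length(ids))
    stop("no such tree in topology", call. = FALSE)
  sid <- ids[tree_index]
  c <- node_index(topo$cat$tree, child)
  if (cat_root_node(topo$cat, sid) == c)
    stop("gene ", child, " is the root of that tree; no incoming link to remove",
         call. = FALSE)
  res <- shape_cut(topo$cat, sid, c)
  if (is.null(res))
    stop("tree ", tree_index, " has no slot link into gene ", child, call. = FALSE)
  topology(topo$cat, c(ids[-tree_index], res$new, res$detached))
}

#' Swap two slot links between trees
#'
#' Disconnects links (n1, p1) and (n2, p2) and reconnects them as (n1, p2)
#' and (n2, p1). Both child slots must belong to the same gene (hence both
#' parent slots to the same parent gene). The numbers of trees and deaths are
#' unchanged.
#'
#' @param topo A \code{ts_topology}.
#' @param link1,link2 Each a list/vector \code{(tree_index, child_label)}
#'   identifying a slot link as in \code{\link{remove_edge}}.
#' @return The new \code{ts_topology}.
#' @export
branch_swap <- function(topo, link1, link2) {
  t1 <- as.integer(link1[[1]]); c1 <- as.character(link1[[2]])
  t2 <- as.integer(link2[[1]]); c2 <- as.character(link2[[2]])
  if (c1 != c2)
    stop("branch swap requires slots from the same gene", call. = FALSE)
  ids <- topo$ids[order(topo$cat$key[topo$ids])]
  if (any(c(t1, t2) < 1) || any(c(t1, t2) > length(ids)))
    stop("no such tree in topology", call. = FALSE)
  c <- node_index(topo$cat$tree, c1)
  if (t1 == t2) {
    # a tree holds at most one slot per gene: only the identity swap exists
    return(topo)
  }
  s1 <- ids[t1]; s2 <- ids[t2]
  cut1 <- shape_cut(topo$cat, s1, c)
  cut2 <- shape_cut(topo$cat, s2, c)
  if (is.null(cut1) || is.null(cut2))
    stop("both trees must have a slot link into gene ", c1, call. = FALSE)
  n1 <- shape_graft(topo$cat, s1, c, cut2$detached)
  n2 <- shape_graft(topo$cat, s2, c, cut1$detached)
  topology(topo$cat, c(ids[-c(t1, t2)], n1, n2))
}

# ---- enumeration -----------------------------------------------------------

#' Enumerate all valid topologies for observed transcript counts
#'
#' Builds, by direct constrained construction, every multiset of proper tree
#' shapes whose leaf-gene coverage equals the observed transcript counts,
#' keeps the structurally valid ones (every gene hosts a slot; gene graph
#' connected), and returns them grouped by increasing number of trees, each
#' group in deterministic canonical-key order with no duplicate keys.
#'
#' @param tree A \code{gene_tree} (or a prebuilt \code{shape_catalog}).
#' @param leaf_counts Named integer vector: observed transcripts per leaf
#'   gene (all >= 1).
#' @param max_trees Upper bound on the number of trees; defaults to the total
#'   transcript count (no topology can have more trees than transcripts).
#' @param max_topologies Guard on the number of candidate multisets explored.
#' @return A list of \code{ts_topology}, ordered by (tree count, key).
#' @export
enumerate_topologies <- function(tree, leaf_counts, max_trees = NULL,
                                 max_topologies = 2000000) {
  cat <- if (inherits(tree, "shape_catalog")) tree else shape_catalog(tree)
  need <- check_leaf_counts(cat, leaf_counts)
  total <- sum(need)
  if (is.null(max_trees)) max_trees <- total
  out <- list()
  if (max_trees >= max(need)) {
    for (t in seq(max(need), max_trees)) {
      out <- c(out, topologies_of_size(cat, need, t, max_topologies))
    }
  }
  out
}

check_leaf_counts <- function(cat, leaf_counts) {
  tree <- cat$tree
  leaf_idx <- node_index(tree, names(leaf_counts))
  if (any(leaf_counts < 1)) stop("leaf counts must be >= 1", call. = FALSE)
  if (!setequal(leaf_idx, which(tree$is_leaf)))
    stop("leaf_counts must cover every leaf gene", call. = FALSE)
  need <- integer(length(tree$label))
  need[leaf_idx] <- as.integer(leaf_counts)
  need
}

# all valid topologies with exactly t trees, in canonical-key order.
# DFS over non-decreasing shape ids; each proper shape covers >= 1 leaf
# slot, which bounds the number of trees still placeable. When per-shape
# lower-bound weights are supplied, any partial multiset whose
# base_cost + sum(weights) already exceeds `bound` is cut (weights are
# non-negative, so the cut is sound).
topologies_of_size <- function(cat, need, t, max_topologies = 2000000,
                               weights = NULL, base_cost = 0, bound = Inf) {
  ok <- which(cat$proper)
  lc <- do.call(rbind, cat$leafcover[ok])
  leaf_cols <- which(colSums(lc) > 0 | need > 0)
  lc <- lc[, leaf_cols, drop = FALSE]
  rem0 <- need[leaf_cols]
  covmax <- max(rowSums(lc))
  w <- if (is.null(weights)) rep(0, length(ok)) else weights[ok]
  out <- list()
  n_explored <- 0L
  recurse <- function(from, remaining, chosen, left, acc) {
    tot <- sum(remaining)
    if (left == 0L) {
      if (tot != 0L) return(invisible(NULL))
      n_explored <<- n_explored + 1L
      if (n_explored > max_topologies)
        stop("topology enumeration exceeds max_topologies", call. = FALSE)
      tp <- topology(cat, ok[chosen])
      if (is_valid_topology(tp)) out[[length(out) + 1L]] <<- tp
      return(invisible(NULL))
    }
    if (tot < left || tot > left * covmax) return(invisible(NULL))
    for (i in seq(from, length(ok))) {
      cv <- lc[i, ]
      if (any(cv > remaining)) next
      acc2 <- acc + w[i]
      if (base_cost + acc2 > bound + 1e-9) next
      recurse(i, remaining - cv, c(chosen, i), left - 1L, acc2)
    }
    invisible(NULL)
  }
  if (t >= 1L) recurse(1L, rem0, integer(0), t, 0)
  keys <- vapply(out, canonical_key, "")
  ord <- order(keys)
  out <- out[ord]
  out[!duplicated(keys[ord])]
}

#' Draw one random valid topology
#'
#' Builds a random base configuration demand-driven (repeatedly attaching a
#' random proper shape that covers the first leaf gene with unmet transcript
#' demand), then applies \code{extra_removals} random edge removals. Used by
#' the sampling initialisation of the search. Respects the current RNG
#' state.
#'
#' @param cat A \code{shape_catalog} (or \code{gene_tree}).
#' @param leaf_counts Named integer vector of transcripts per leaf gene.
#' @param extra_removals Number of random edge removals to apply.
#' @param max_tries Attempts before giving up (returns \code{NULL}).
#' @return A valid \code{ts_topology}, or \code{NULL}.
#' @export
random_topology <- function(cat, leaf_counts, extra_removals = 0L,
                            max_tries = 25L) {
  if (inherits(cat, "gene_tree")) cat <- shape_catalog(cat)
  need <- check_leaf_counts(cat, leaf_counts)
  tree <- cat$tree
  ok <- which(cat$proper)
  lc <- do.call(rbind, cat$leafcover[ok])
  leaf_nodes <- which(tree$is_leaf)
  for (try in seq_len(max_tries)) {
    remaining <- need
    chosen <- integer(0)
    repeat {
      unmet <- leaf_nodes[remaining[leaf_nodes] > 0L]
      if (!length(unmet)) break
      g <- unmet[1]
      cand <- which(lc[, g] > 0L)
      cand <- cand[vapply(cand, function(i) all(lc[i, ] <= remaining), TRUE)]
      if (!length(cand)) { chosen <- NULL; break }
      i <- cand[sample.int(length(cand), 1L)]
      remaining <- remaining - lc[i, ]
      chosen <- c(chosen, i)
    }
    if (is.null(chosen)) next
    tp <- topology(cat, ok[chosen])
    r <- 0L
    while (r < extra_removals) {
      links <- topology_links(tp)
      if (!nrow(links)) break
      pick <- links[sample.int(nrow(links), 1L), ]
      tp <- remove_edge(tp, pick$tree, pick$child)
      r <- r + 1L
    }
    if (r == extra_removals && is_valid_topology(tp)) return(tp)
  }
  NULL
}

# all slot links of a topology as (tree index in canonical order, child gene)
topology_links <- function(topo) {
  cat <- topo$cat
  ids <- topo$ids[order(cat$key[topo$ids])]
  rows <- list()
  walk <- function(sid, tix) {
    for (cs in c(cat$left[sid], cat$right[sid])) {
      if (is.na(cs)) next
      rows[[length(rows) + 1L]] <<- data.frame(
        tree = tix, child = cat$tree$label[cat$node[cs]],
        stringsAsFactors = FALSE)
      walk(cs, tix)
    }
  }
  for (k in seq_along(ids)) walk(ids[k], k)
  if (!length(rows)) {
    return(data.frame(tree = integer(0), child = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# ---- instantiation & guide tree -------------------------------------------

# lay out concrete slots for the leaf-assignment machinery
instantiate_topology <- function(topo) {
  cat <- topo$cat; tree <- cat$tree
  ids <- topo$ids[order(cat$key[topo$ids])]
  slot_gene <- integer(0); slot_tree <- integer(0); slot_shape <- integer(0)
  slot_left <- integer(0); slot_right <- integer(0)
  add_slot <- function(tix, sid) {
    j <- length(slot_gene) + 1L
    slot_gene[j] <<- cat$node[sid]; slot_tree[j] <<- tix; slot_shape[j] <<- sid
    slot_left[j] <<- NA_integer_; slot_right[j] <<- NA_integer_
    l <- cat$left[sid]; r <- cat$right[sid]
    if (!is.na(l)) slot_left[j] <<- add_slot(tix, l)
    if (!is.na(r)) slot_right[j] <<- add_slot(tix, r)
    j
  }
  root_slots <- integer(length(ids))
  for (tix in seq_along(ids)) root_slots[tix] <- add_slot(tix, ids[tix])
  n <- length(tree$label)
  slots_of_gene <- vector("list", n)
  for (v in seq_len(n)) slots_of_gene[[v]] <- which(slot_gene == v)
  list(topo = topo, tree = tree, ids = ids,
       slot_gene = slot_gene, slot_tree = slot_tree, slot_shape = slot_shape,
       slot_left = slot_left, slot_right = slot_right,
       root_slots = root_slots, slots_of_gene = slots_of_gene)
}

#' Build the guide tree of a topology
#'
#' Groups, per gene, the topology's transcript slots into boxes keyed by
#' identical subtree shape; the dot count of a box is the number of slots
#' sharing that shape. The guide tree constrains which child-slot pointers
#' are feasible during leaf assignment: a slot can only point to a child slot
#' whose subtree shape matches.
#'
#' @param topo A \code{ts_topology}.
#' @return An object of class \code{guide_tree}: a named list (per gene
#'   label) of data frames with columns \code{shape} and \code{dots}.
#' @export
build_guide_tree <- function(topo) {
  inst <- instantiate_topology(topo)
  cat <- topo$cat; tree <- cat$tree
  out <- list()
  for (v in seq_along(tree$label)) {
    sl <- inst$slots_of_gene[[v]]
    if (!length(sl)) next
    tab <- table(cat$key[inst$slot_shape[sl]])
    out[[tree$label[v]]] <- data.frame(shape = names(tab),
                                       dots = as.integer(tab),
                                       stringsAsFactors = FALSE)
  }
  structure(out, class = "guide_tree")
}

#' @export
print.guide_tree <- function(x, ...) {
  for (g in names(x)) {
    cat(g, ":\n", sep = "")
    for (i in seq_len(nrow(x[[g]])))
      cat("  [", x[[g]]$dots[i], "] ", x[[g]]$shape[i], "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a topology to JSON
#'
#' @param topo A \code{ts_topology}.
#' @return A JSON string listing the tree shapes, tree count and death count.
#' @export
topology_to_json <- function(topo) {
  jsonlite::toJSON(list(trees = sort(topo$cat$key[topo$ids]),
                        n_tree = n_trees(topo), n_death = n_deaths(topo)),
                   auto_unbox = TRUE)
}
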