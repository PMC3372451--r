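# Core domain types: rooted binary gene trees, transcript matrices, exon
# columns, cost parameters, and instance I/O (Newick + TSV).

# Exon states at the gene level. Integer codes are used internally; the
# TSV dump uses the tokens "0", "1A", "1C".
EXON_ABSENT <- 0L
EXON_ALTERNATIVE <- 1L
EXON_CONSTITUTIVE <- 2L

#' Exon state labels
#'
#' The three gene-level exon states: an exon column is absent from the gene,
#' alternative (spliced into some transcripts), or constitutive (spliced into
#' all transcripts). Internally states are coded 0, 1, 2 in this order.
#'
#' @return Character vector of the three state labels, in code order.
#' @export
exon_states <- function() c("absent", "alternative", "constitutive")

state_token <- function(code) c("0", "1A", "1C")[code + 1L]

#' Build a gene tree from an ape \code{phylo} object
#'
#' Gene trees must be rooted and strictly binary: every internal node has
#' exactly two children. Multifurcations are rejected because the leaf
#' assignment recursion assumes two child genes per ancestral gene. Tip
#' labels must be unique; internal nodes are labelled from the Newick node
#' labels when present, otherwise as \code{n<k>}.
#'
#' @param phy An object of class \code{phylo} (see \code{\link[ape]{read.tree}}).
#' @return An object of class \code{gene_tree}: a list with elements
#'   \code{label}, \code{parent}, \code{left}, \code{right}, \code{is_leaf}
#'   (per-node vectors), \code{root} (node index) and \code{postorder}
#'   (children before parents).
#' @export
as_gene_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected an ape 'phylo' object", call. = FALSE)
  if (!ape::is.rooted(phy)) stop("gene tree must be rooted", call. = FALSE)
  if (!ape::is.binary(phy)) {
    stop("gene tree must be strictly binary (multifurcations are not supported)",
         call. = FALSE)
  }
  ntip <- length(phy$tip.label)
  if (anyDuplicated(phy$tip.label)) stop("leaf names must be unique", call. = FALSE)
  n <- ntip + phy$Nnode
  label <- character(n)
  label[seq_len(ntip)] <- phy$tip.label
  if (!is.null(phy$node.label) && all(nzchar(phy$node.label))) {
    label[ntip + seq_len(phy$Nnode)] <- phy$node.label
  } else {
    label[ntip + seq_len(phy$Nnode)] <- paste0("n", seq_len(phy$Nnode))
  }
  if (anyDuplicated(label)) stop("node labels must be unique", call. = FALSE)
  parent <- rep(NA_integer_, n)
  left <- rep(NA_integer_, n)
  right <- rep(NA_integer_, n)
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    parent[ch] <- p
    if (is.na(left[p])) left[p] <- ch else right[p] <- ch
  }
  root <- which(is.na(parent))
  is_leaf <- seq_len(n) <= ntip
  # postorder: children before parents
  post <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    post <- c(post, v)
    if (!is_leaf[v]) stack <- c(stack, left[v], right[v])
  }
  post <- rev(post)
  structure(
    list(label = label, parent = parent, left = left, right = right,
         is_leaf = is_leaf, root = root, postorder = post),
    class = "gene_tree")
}

#' Read a gene tree from a Newick file
#'
#' @param path Path to a Newick file containing a single rooted binary tree.
#' @return A \code{gene_tree} object.
#' @export
read_gene_tree <- function(path) {
  if (!file.exists(path)) stop("gene tree file not found: ", path, call. = FALSE)
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick file: ", path, call. = FALSE)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  as_gene_tree(phy)
}

#' Convert a gene tree back to an ape \code{phylo}
#'
#' @param tree A \code{gene_tree}.
#' @return An ape \code{phylo} object with node labels preserved.
#' @export
gene_tree_to_phylo <- function(tree) {
  nwk <- paste0(newick_of_node(tree, tree$root), ";")
  ape::read.tree(text = nwk)
}

newick_of_node <- function(tree, v) {
  if (tree$is_leaf[v]) return(tree$label[v])
  paste0("(", newick_of_node(tree, tree$left[v]), ",",
         newick_of_node(tree, tree$right[v]), ")", tree$label[v])
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("Gene tree with", sum(x$is_leaf), "leaf genes:",
      paste(x$label[x$is_leaf], collapse = ", "), "\n")
  invisible(x)
}

n_leaves <- function(tree) sum(tree$is_leaf)

tree_depth <- function(tree) {
  depth <- integer(length(tree$label))
  for (v in rev(tree$postorder)) {
    if (!is.na(tree$parent[v])) depth[v] <- depth[tree$parent[v]] + 1L
  }
  max(depth[tree$is_leaf])
}

node_index <- function(tree, label) {
  i <- match(label, tree$label)
  if (anyNA(i)) stop("unknown gene name(s): ", paste(label[is.na(i)], collapse = ", "),
                     call. = FALSE)
  i
}

# ancestors of v (excluding v), root last
node_ancestors <- function(tree, v) {
  out <- integer(0)
  while (!is.na(tree$parent[v])) { v <- tree$parent[v]; out <- c(out, v) }
  out
}

#' Cost parameters of the transcript-evolution model
#'
#' @param c_B Cost of a transcript birth (a new transcript tree). May be
#'   \code{Inf}.
#' @param c_D Cost of a transcript death.
#' @param c_E Cost of a transcript-level exon gain or loss, i.e. the
#'   off-diagonal entry of the exon-configuration transition cost
#'   \code{c(a, b)}. \code{Inf} forbids transcript-level changes, so a
#'   transcript tree scores 0 or \code{Inf}. Gene-level events (constitutive
#'   exon gain, exon loss) always cost 0 at the transcript level.
#' @return An object of class \code{ts_costs}.
#' @export
ts_costs <- function(c_B = 1, c_D = 1, c_E = 1) {
  for (v in list(c_B = c_B, c_D = c_D, c_E = c_E)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop("costs must be single non-negative numbers (Inf allowed)", call. = FALSE)
  }
  structure(list(c_B = c_B, c_D = c_D, c_E = c_E), class = "ts_costs")
}

#' Assemble a transcript-phylogeny instance
#'
#' @param tree A \code{gene_tree}.
#' @param transcripts Named list, one entry per leaf gene, each an integer
#'   matrix with one row per transcript (rownames are transcript ids) and one
#'   column per orthologous exon column. Value 0 means the exon is excluded
#'   from the transcript; k >= 1 means it is included in configuration k
#'   (k > 1 is used for exons with several internal states, e.g. alternative
#'   3'/5' splice sites).
#' @param columns Optional character vector of exon-column ids; defaults to
#'   the column names of the first matrix.
#' @return An object of class \code{ts_instance} with elements \code{tree},
#'   \code{transcripts}, \code{columns} and \code{alphabet} (per-column
#'   maximum configuration, >= 1).
#' @export
ts_instance <- function(tree, transcripts, columns = NULL) {
  stopifnot(inherits(tree, "gene_tree"))
  if (is.null(names(transcripts)) || !all(nzchar(names(transcripts))))
    stop("'transcripts' must be a named list keyed by leaf gene", call. = FALSE)
  leaves <- tree$label[tree$is_leaf]
  bad <- setdiff(names(transcripts), leaves)
  if (length(bad))
    stop("unknown gene name(s) in transcript data: ", paste(bad, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(leaves, names(transcripts))
  if (length(missing))
    stop("leaf gene(s) without transcripts: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(columns)) columns <- colnames(transcripts[[1]])
  if (is.null(columns)) columns <- paste0("e", seq_len(ncol(transcripts[[1]])))
  transcripts <- transcripts[leaves]
  all_ids <- character(0)
  for (g in leaves) {
    m <- transcripts[[g]]
    if (!is.matrix(m)) m <- matrix(as.integer(m), nrow = 1)
    storage.mode(m) <- "integer"
    if (ncol(m) != length(columns))
      stop("transcript matrix for gene ", g, " has ", ncol(m),
           " columns, expected ", length(columns), call. = FALSE)
    if (nrow(m) < 1) stop("leaf gene ", g, " has zero transcripts", call. = FALSE)
    if (anyNA(m) || any(m < 0))
      stop("transcript values must be non-negative integers (gene ", g, ")",
           call. = FALSE)
    if (is.null(rownames(m))) rownames(m) <- paste0(g, ".t", seq_len(nrow(m)))
    colnames(m) <- columns
    transcripts[[g]] <- m
    all_ids <- c(all_ids, rownames(m))
  }
  if (anyDuplicated(all_ids))
    stop("transcript ids must be unique across the instance", call. = FALSE)
  alphabet <- rep(1L, length(columns))
  for (g in leaves) alphabet <- pmax(alphabet, apply(transcripts[[g]], 2, max))
  names(alphabet) <- columns
  structure(list(tree = tree, transcripts = transcripts,
                 columns = columns, alphabet = as.integer(alphabet)),
            class = "ts_instance")
}

#' @export
print.ts_instance <- function(x, ...) {
  k <- vapply(x$transcripts, nrow, 1L)
  cat("Transcript instance:", length(k), "leaf genes,",
      sum(k), "transcripts,", length(x$columns), "exon columns\n")
  invisible(x)
}

#' Read an instance from a Newick gene tree and a TSV transcript matrix
#'
#' The TSV has a header row and columns \code{transcript_id}, \code{gene_id},
#' followed by one integer column per orthologous exon column (0 = excluded,
#' k >= 1 = included in configuration k). Paralogous exons are expected to be
#' encoded as distinct columns; ortholog grouping is the caller's
#' responsibility.
#'
#' @param gene_tree_path Path to the Newick file.
#' @param transcript_matrix_path Path to the TSV matrix.
#' @return A validated \code{ts_instance}.
#' @export
read_instance <- function(gene_tree_path, transcript_matrix_path) {
  tree <- read_gene_tree(gene_tree_path)
  if (!file.exists(transcript_matrix_path))
    stop("transcript matrix file not found: ", transcript_matrix_path, call. = FALSE)
  tab <- utils::read.delim(transcript_matrix_path, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("transcript_id", "gene_id")
  if (!all(need %in% colnames(tab)))
    stop("TSV must have 'transcript_id' and 'gene_id' columns", call. = FALSE)
  cols <- setdiff(colnames(tab), need)
  if (!length(cols)) stop("TSV has no exon columns", call. = FALSE)
  vals <- as.matrix(tab[, cols, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals) || any(vals != round(vals)) || any(vals < 0))
    stop("exon column values must be non-negative integers", call. = FALSE)
  storage.mode(vals) <- "integer"
  leaves <- tree$label[tree$is_leaf]
  bad <- setdiff(unique(tab$gene_id), leaves)
  if (length(bad))
    stop("unknown gene name(s) in transcript matrix: ", paste(bad, collapse = ", "),
         call. = FALSE)
  transcripts <- lapply(split(seq_len(nrow(tab)), factor(tab$gene_id, levels = leaves)),
                        function(i) {
                          m <- vals[i, , drop = FALSE]
                          rownames(m) <- tab$transcript_id[i]
                          m
                        })
  ts_instance(tree, transcripts, columns = cols)
}

#' Write an instance to a Newick file and a TSV transcript matrix
#'
#' Inverse of \code{\link{read_instance}}: the written files read back to an
#' instance identical in all fields.
#'
#' @param instance A \code{ts_instance}.
#' @param gene_tree_path,transcript_matrix_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_instance <- function(instance, gene_tree_path, transcript_matrix_path) {
  stopifnot(inherits(instance, "ts_instance"))
  writeLines(paste0(newick_of_node(instance$tree, instance$tree$root), ";"),
             gene_tree_path)
  rows <- list()
  for (g in names(instance$transcripts)) {
    m <- instance$transcripts[[g]]
    rows[[g]] <- data.frame(transcript_id = rownames(m), gene_id = g,
                            m, check.names = FALSE, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, transcript_matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(gene_tree_path, transcript_matrix_path))
}
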