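# Distance-based neighbor-joining phylogenetics with bootstrap support and
# sister-pair (cherry) extraction.
#
# Distances are uncorrected p-distances on a multiple protein alignment;
# tree construction is Saitou-Nei neighbor joining (via ape); bootstrap
# support is the fraction of column-resampled replicate trees containing
# each original bipartition.

.aln_matrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- aln
  } else {
    if (inherits(aln, "seq_record")) aln <- list(aln)
    seqs <- vapply(aln, function(r) {
      if (inherits(r, "seq_record")) r$sequence else toupper(r)
    }, character(1L))
    ids <- if (!is.null(names(aln)) && all(nzchar(names(aln)))) {
      names(aln)
    } else {
      vapply(aln, function(r) if (inherits(r, "seq_record")) r$id else NA_character_,
             character(1L))
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop("aligned sequences must have equal length")
    }
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- ids
  }
  if (nrow(m) < 2L) stop("alignment must contain at least two sequences")
  m
}

#' Pairwise p-distance matrix from a protein alignment
#'
#' For each pair, the proportion of differing sites over the columns where
#' neither sequence has a gap.
#'
#' @param aln Named list of aligned [seq_record()]s / gapped strings, or a
#'   character matrix (rows = sequences).
#' @return A symmetric `dist`-compatible square matrix with zero diagonal.
#' @export
pdistance_matrix <- function(aln) {
  m <- .aln_matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        stop("no comparable (gap-free) columns between '", rownames(m)[i],
             "' and '", rownames(m)[j], "'")
      }
      d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining. The input label order does not affect the
#' topology; ties in the Q-matrix are resolved deterministically.
#'
#' @param dm Symmetric distance matrix with row/column labels (>= 3 taxa).
#' @return An [ape::phylo] tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) < 3L) {
    stop("neighbor joining requires at least 3 taxa")
  }
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix is not symmetric")
  ape::nj(stats::as.dist(dm))
}

#' Bootstrap support for a neighbor-joining protein tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' NJ tree from the p-distances of each replicate, and reports for each
#' internal edge of the original tree the fraction of replicates containing
#' the same bipartition. Supports are attached as `node.label`.
#'
#' @param aln Alignment as for [pdistance_matrix()].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; replicates are drawn deterministically from it.
#' @return The original NJ tree with `node.label` set to support
#'   proportions in `[0, 1]` (root label empty).
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  m <- .aln_matrix(aln)
  tree <- nj_tree(pdistance_matrix(m))
  set.seed(seed)
  n_col <- ncol(m)
  boot_trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(n_col, n_col, replace = TRUE)
    boot_trees[[r]] <- nj_tree(pdistance_matrix(m[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- counts / n_reps
  tree
}

#' Extract well-supported sister pairs (cherries) from a tree
#'
#' Leaf pairs that are mutual nearest neighbors (share an immediate
#' ancestor) with bootstrap support at least `min_support`.
#'
#' @param tree An [ape::phylo] tree whose `node.label` holds support
#'   proportions (as from [bootstrap_support()]). A tree without node
#'   labels is treated as fully supported.
#' @param min_support Minimum support proportion (default 0.5).
#' @return Data frame with columns `gene_a`, `gene_b`, `support`, one row
#'   per reported cherry (alphabetical within pair, sorted by `gene_a`).
#' @export
sister_pairs <- function(tree, min_support = 0.5) {
  n_tip <- length(tree$tip.label)
  parent_of_tip <- tree$edge[match(seq_len(n_tip), tree$edge[, 2L]), 1L]
  supports <- tree$node.label
  rows <- list()
  for (node in unique(parent_of_tip)) {
    tips <- which(parent_of_tip == node)
    if (length(tips) != 2L) next
    sup <- if (is.null(supports)) 1 else {
      s <- supports[node - n_tip]
      if (is.na(s) || !nzchar(as.character(s))) 1 else as.numeric(s)
    }
    if (sup < min_support) next
    pair <- sort(tree$tip.label[tips])
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = pair[1L], gene_b = pair[2L], support = sup,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      support = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$gene_a), , drop = FALSE]
}
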