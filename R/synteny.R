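# Microsynteny detection around anchor gene pairs and the synteny-quality
# statistic.
#
# A block is reported when three or more conserved homolog pairs (anchor
# included by default) lie within the 100-kb windows flanking the two
# anchors. Homology is a best-non-self local-alignment match (BLOSUM62,
# affine gaps) above a score threshold calibrated so that unrelated random
# proteins pass at well under 0.1%. A block is flagged as originating from a
# large-scale duplication when five or more flanking (non-anchor)
# protein-coding gene pairs are matched. Synteny quality is
# 100 * 2P / (Ga + Gb): conserved pairs over total genes in both segments,
# after excluding retroelements/transposons and collapsing tandem arrays.

.aln_score_matrix <- function(seqs_a, seqs_b, gap_opening = 10,
                              gap_extension = 0.5) {
  set_a <- Biostrings::AAStringSet(vapply(seqs_a, function(r) r$sequence,
                                          character(1L)))
  names(set_a) <- vapply(seqs_a, function(r) r$id, character(1L))
  m <- matrix(NA_real_, length(seqs_a), length(seqs_b),
              dimnames = list(names(set_a),
                              vapply(seqs_b, function(r) r$id, character(1L))))
  for (j in seq_along(seqs_b)) {
    m[, j] <- Biostrings::pairwiseAlignment(
      set_a, Biostrings::AAString(seqs_b[[j]]$sequence),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening, gapExtension = gap_extension,
      scoreOnly = TRUE)
  }
  m
}

#' Match homologs between two protein sets
#'
#' For each protein in set A, finds its best non-self-scoring partner in set
#' B under Smith-Waterman local alignment (BLOSUM62, affine gaps) and keeps
#' the match when the score reaches `threshold`. A `reciprocal` flag records
#' whether the partner's own best non-self match in A is the same pair.
#'
#' @param proteins_a,proteins_b Lists of protein [seq_record()]s. Records
#'   with the same id in both sets are never matched to themselves.
#' @param threshold Minimum local-alignment score (default 150, calibrated on
#'   a seeded random-protein null so unrelated proteins score far below it).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Data frame with columns `gene_a`, `gene_b`, `score`,
#'   `is_best_non_self` (always `TRUE` for reported rows), `reciprocal`.
#' @export
match_homologs <- function(proteins_a, proteins_b, threshold = 150,
                           gap_opening = 10, gap_extension = 0.5) {
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), is_best_non_self = logical(0),
                      reciprocal = logical(0), stringsAsFactors = FALSE)
  if (length(proteins_a) == 0L || length(proteins_b) == 0L) {
    warning("empty protein set; no homolog matches")
    return(empty)
  }
  m <- .aln_score_matrix(proteins_a, proteins_b, gap_opening, gap_extension)
  # self matches (same id) are excluded from "best non-self"
  self <- outer(rownames(m), colnames(m), "==")
  m_masked <- m
  m_masked[self] <- -Inf
  rows <- list()
  for (i in seq_len(nrow(m))) {
    j <- which.max(m_masked[i, ])
    sc <- m_masked[i, j]
    if (!is.finite(sc) || sc < threshold) next
    back <- which.max(m_masked[, j])
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = rownames(m)[i], gene_b = colnames(m)[j], score = sc,
      is_best_non_self = TRUE, reciprocal = back == i,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

.segment_genes <- function(ann, chrom, start, end) {
  keep <- vapply(ann$genes, function(g) {
    if (g$chromosome != chrom) return(FALSE)
    if (!is.null(ann$gene_class_tags)) {
      tag <- ann$gene_class_tags[[g$gene_id]]
      if (!is.null(tag) && !is.na(tag) &&
          tag %in% c("retroelement", "transposon")) {
        return(FALSE)
      }
    }
    gene_start(g) >= start && gene_end(g) <= end
  }, logical(1L))
  ann$genes[keep]
}

# Collapse tandem arrays inside a segment to one representative per array
# (the 5'-most gene), reusing the tandem rule of the duplication module:
# two segment genes are in one array when they are homologous (local score
# >= threshold) and satisfy is_tandem_pair().
.collapse_tandem <- function(genes, ann, proteome, threshold,
                             max_intervening = 5L, window = 1e5,
                             keep_ids = character(0)) {
  if (length(genes) < 2L) return(genes)
  recs <- proteome[intersect(names(genes), names(proteome))]
  if (length(recs) < 2L) return(genes)
  m <- .aln_score_matrix(recs, recs)
  keep <- rep(TRUE, length(genes))
  names(keep) <- names(genes)
  # anchors are never collapsed away; order them first so that a colliding
  # array drops its other members instead
  ord <- names(genes)[order(!(names(genes) %in% keep_ids),
                            vapply(genes, gene_start, numeric(1L)))]
  for (i in seq_along(ord)) {
    if (!keep[[ord[i]]]) next
    for (j in seq_along(ord)) {
      if (j <= i || !keep[[ord[j]]]) next
      gi <- ord[i]; gj <- ord[j]
      if (gj %in% keep_ids) next
      if (!gi %in% rownames(m) || !gj %in% rownames(m)) next
      if (m[gi, gj] >= threshold &&
          is_tandem_pair(genes[[gi]], genes[[gj]], ann,
                         max_intervening, window)) {
        keep[[gj]] <- FALSE
      }
    }
  }
  genes[keep]
}

#' Detect a microsynteny block around an anchor gene pair
#'
#' Collects the genes in the `window`-bp flanks of each anchor (excluding
#' retroelements/transposons and collapsing tandem arrays), matches
#' homologs between the two segments, and reports a block when at least
#' `min_pairs` conserved pairs are found (the anchor pair counting by
#' default). The relative orientation of the paired genes is recorded as
#' `"same"` or `"inverted"` from the rank correlation of their positions.
#'
#' @param anchor_a,anchor_b Anchor [gene_model()]s in their respective
#'   annotations.
#' @param ann_a,ann_b [annotation()]s of the two genomes (may be the same
#'   object for within-genome comparisons).
#' @param proteome_a,proteome_b Named lists of protein [seq_record()]s.
#' @param window Flank size in bp on each side of an anchor (default
#'   100000).
#' @param threshold Homolog score threshold (see [match_homologs()]).
#' @param min_pairs Minimum conserved pairs for a block (default 3).
#' @param count_anchor Whether the anchor pair counts toward `min_pairs`
#'   (default `TRUE`).
#' @param collapse_tandem Collapse tandem arrays inside segments (default
#'   `TRUE`).
#' @return A `synteny_block` object, or `NULL` when the criterion is not
#'   met. Fields: `anchor_pair`, `segment_a`, `segment_b` (chrom/start/end),
#'   `genes_a`, `genes_b` (ids after filtering), `conserved_pairs` (data
#'   frame), `orientation`, `large_scale`, `quality_pct`.
#' @export
detect_block <- function(anchor_a, anchor_b, ann_a, ann_b,
                         proteome_a, proteome_b, window = 1e5,
                         threshold = 150, min_pairs = 3L,
                         count_anchor = TRUE, collapse_tandem = TRUE) {
  seg_bounds <- function(anchor, ann) {
    len <- ann$chromosome_lengths[[anchor$chromosome]]
    c(max(0, gene_start(anchor) - window),
      min(len, gene_end(anchor) + window))
  }
  ba <- seg_bounds(anchor_a, ann_a)
  bb <- seg_bounds(anchor_b, ann_b)
  genes_a <- .segment_genes(ann_a, anchor_a$chromosome, ba[1L], ba[2L])
  genes_b <- .segment_genes(ann_b, anchor_b$chromosome, bb[1L], bb[2L])
  if (collapse_tandem) {
    genes_a <- .collapse_tandem(genes_a, ann_a, proteome_a, threshold,
                                keep_ids = anchor_a$gene_id)
    genes_b <- .collapse_tandem(genes_b, ann_b, proteome_b, threshold,
                                keep_ids = anchor_b$gene_id)
  }
  prots_a <- proteome_a[intersect(names(genes_a), names(proteome_a))]
  prots_b <- proteome_b[intersect(names(genes_b), names(proteome_b))]
  pairs <- suppressWarnings(match_homologs(prots_a, prots_b, threshold))
  # anchors are homologous by premise; make sure the anchor pair is present
  is_anchor <- pairs$gene_a == anchor_a$gene_id &
    pairs$gene_b == anchor_b$gene_id
  if (!any(is_anchor)) {
    sc <- if (length(prots_a) > 0L && anchor_a$gene_id %in% names(prots_a) &&
              anchor_b$gene_id %in% names(prots_b)) {
      .aln_score_matrix(prots_a[anchor_a$gene_id],
                        prots_b[anchor_b$gene_id])[1L, 1L]
    } else NA_real_
    pairs <- rbind(pairs, data.frame(
      gene_a = anchor_a$gene_id, gene_b = anchor_b$gene_id, score = sc,
      is_best_non_self = FALSE, reciprocal = FALSE, stringsAsFactors = FALSE))
    is_anchor <- c(rep(FALSE, nrow(pairs) - 1L), TRUE)
  }
  pairs$is_anchor <- is_anchor
  n_eff <- if (count_anchor) nrow(pairs) else sum(!pairs$is_anchor)
  if (n_eff < min_pairs) return(NULL)

  orientation <- "same"
  if (nrow(pairs) >= 2L) {
    pos_a <- vapply(pairs$gene_a, function(id) gene_start(genes_a[[id]]),
                    numeric(1L))
    pos_b <- vapply(pairs$gene_b, function(id) gene_start(genes_b[[id]]),
                    numeric(1L))
    rho <- suppressWarnings(stats::cor(pos_a, pos_b, method = "spearman"))
    if (is.finite(rho) && rho < 0) orientation <- "inverted"
  }
  block <- structure(list(
    anchor_pair = c(anchor_a$gene_id, anchor_b$gene_id),
    segment_a = list(chrom = anchor_a$chromosome, start = ba[1L], end = ba[2L]),
    segment_b = list(chrom = anchor_b$chromosome, start = bb[1L], end = bb[2L]),
    genes_a = names(genes_a), genes_b = names(genes_b),
    conserved_pairs = pairs, orientation = orientation),
    class = "synteny_block")
  block$large_scale <- is_large_scale_duplication(block)
  block$quality_pct <- synteny_quality(block)
  block
}

#' @export
print.synteny_block <- function(x, ...) {
  cat(sprintf(
    "<synteny_block %s~%s: %d pair(s), %d+%d genes, %s, large_scale=%s, quality=%.1f%%>\n",
    x$anchor_pair[1L], x$anchor_pair[2L], nrow(x$conserved_pairs),
    length(x$genes_a), length(x$genes_b), x$orientation, x$large_scale,
    x$quality_pct))
  invisible(x)
}

#' Large-scale duplication test for a synteny block
#'
#' `TRUE` iff at least `min_flanking` flanking (non-anchor) gene pairs are
#' best-non-self homolog matches.
#'
#' @param block A `synteny_block`.
#' @param min_flanking Minimum flanking pairs (default 5).
#' @return Logical scalar.
#' @export
is_large_scale_duplication <- function(block, min_flanking = 5L) {
  sum(!block$conserved_pairs$is_anchor &
        block$conserved_pairs$is_best_non_self) >= min_flanking
}

#' Synteny quality of a block
#'
#' `100 * 2P / (Ga + Gb)` where `P` is the number of conserved homolog
#' pairs and `Ga`, `Gb` the gene counts of the two segments after
#' retroelement/transposon exclusion and tandem collapsing.
#'
#' @param block A `synteny_block`.
#' @return Percentage in `[0, 100]`.
#' @export
synteny_quality <- function(block) {
  ga <- length(block$genes_a)
  gb <- length(block$genes_b)
  if (ga == 0L || gb == 0L) stop("empty synteny segment")
  100 * 2 * nrow(block$conserved_pairs) / (ga + gb)
}
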