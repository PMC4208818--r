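# Duplicate-pair classification: tandem (T), segmental (S) or other (O),
# plus detection of family genes on duplicated blocks whose sister gene was
# lost.
#
# Tandem rule: same chromosome, at most `max_intervening` annotated genes
# strictly between the pair, and the span from the 5'-most gene start to the
# 3'-most gene end at most `window` bp (defaults 5 genes / 100 kb).
# Segmental rule: the two genes lie on the two partner intervals of a
# duplicated chromosomal block. Tandem takes precedence when both fire.

#' Construct a duplicated block set
#'
#' @param blocks Data frame with columns `block_id`, `chrom_a`, `start_a`,
#'   `end_a`, `chrom_b`, `start_b`, `end_b` (0-based half-open intervals).
#' @return Object of class `duplicated_block_set`.
#' @export
duplicated_block_set <- function(blocks) {
  need <- c("block_id", "chrom_a", "start_a", "end_a",
            "chrom_b", "start_b", "end_b")
  missing <- setdiff(need, names(blocks))
  if (length(missing) > 0L) {
    stop("block table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(blocks$end_a <= blocks$start_a) || any(blocks$end_b <= blocks$start_b)) {
    stop("block intervals must be non-empty 0-based half-open ranges")
  }
  structure(list(blocks = blocks), class = "duplicated_block_set")
}

.gene_in_interval <- function(gene, chrom, start, end) {
  gene$chromosome == chrom && gene_start(gene) >= start && gene_end(gene) <= end
}

#' Tandem-duplicate test for a gene pair
#'
#' @param a,b Distinct [gene_model()]s.
#' @param ann The [annotation()] providing the intervening gene census.
#' @param max_intervening Maximum number of annotated genes strictly between
#'   the pair (default 5).
#' @param window Maximum span in bp from the 5'-most gene start to the
#'   3'-most gene end (default 100000).
#' @param coding_only Count only genes tagged `protein_coding` as
#'   intervening (default `FALSE`: all annotated genes count).
#' @return Logical scalar.
#' @export
is_tandem_pair <- function(a, b, ann, max_intervening = 5L, window = 1e5,
                           coding_only = FALSE) {
  if (identical(a$gene_id, b$gene_id)) stop("a and b must be distinct genes")
  if (a$chromosome != b$chromosome) return(FALSE)
  lo <- min(gene_start(a), gene_start(b))
  hi <- max(gene_end(a), gene_end(b))
  if (hi - lo > window) return(FALSE)
  between <- vapply(ann$genes, function(g) {
    if (g$gene_id %in% c(a$gene_id, b$gene_id)) return(FALSE)
    if (g$chromosome != a$chromosome) return(FALSE)
    if (coding_only && !is.null(ann$gene_class_tags)) {
      tag <- ann$gene_class_tags[[g$gene_id]]
      if (!is.null(tag) && !is.na(tag) && tag != "protein_coding") return(FALSE)
    }
    gene_start(g) >= lo && gene_end(g) <= hi
  }, logical(1L))
  sum(between) <= max_intervening
}

#' Classify a duplicate pair as tandem, segmental or other
#'
#' `T` if the pair satisfies the tandem rule; else `S` if one gene lies in
#' one interval of some duplicated block and the other gene in its partner
#' interval; else `O` (other events, e.g. retrotransposition).
#'
#' @param a,b [gene_model()]s of the pair.
#' @param blocks A [duplicated_block_set()] (may have zero rows).
#' @param ann The [annotation()].
#' @inheritParams is_tandem_pair
#' @return List with `pair` (the two gene ids) and `duplicate_type`
#'   (`"T"`, `"S"` or `"O"`).
#' @export
assign_duplicate_type <- function(a, b, blocks, ann, max_intervening = 5L,
                                  window = 1e5, coding_only = FALSE) {
  type <- if (is_tandem_pair(a, b, ann, max_intervening, window, coding_only)) {
    "T"
  } else {
    seg <- FALSE
    bl <- blocks$blocks
    for (i in seq_len(nrow(bl))) {
      a_in_1 <- .gene_in_interval(a, bl$chrom_a[i], bl$start_a[i], bl$end_a[i])
      a_in_2 <- .gene_in_interval(a, bl$chrom_b[i], bl$start_b[i], bl$end_b[i])
      b_in_1 <- .gene_in_interval(b, bl$chrom_a[i], bl$start_a[i], bl$end_a[i])
      b_in_2 <- .gene_in_interval(b, bl$chrom_b[i], bl$start_b[i], bl$end_b[i])
      if ((a_in_1 && b_in_2) || (a_in_2 && b_in_1)) {
        seg <- TRUE
        break
      }
    }
    if (seg) "S" else "O"
  }
  list(pair = c(a$gene_id, b$gene_id), duplicate_type = type)
}

#' Family genes on duplicated blocks whose sister was lost
#'
#' Returns the family genes located inside one interval of a duplicated
#' block whose partner interval contains no family gene.
#'
#' @param family_genes Character vector of family gene ids.
#' @param blocks A [duplicated_block_set()].
#' @param ann The [annotation()].
#' @return Character vector of singleton gene ids (unique, sorted).
#' @export
find_singletons_on_blocks <- function(family_genes, blocks, ann) {
  fam <- ann$genes[intersect(family_genes, names(ann$genes))]
  singletons <- character(0)
  bl <- blocks$blocks
  for (i in seq_len(nrow(bl))) {
    in_1 <- vapply(fam, .gene_in_interval, logical(1L),
                   chrom = bl$chrom_a[i], start = bl$start_a[i], end = bl$end_a[i])
    in_2 <- vapply(fam, .gene_in_interval, logical(1L),
                   chrom = bl$chrom_b[i], start = bl$start_b[i], end = bl$end_b[i])
    if (any(in_1) && !any(in_2)) singletons <- c(singletons, names(fam)[in_1])
    if (any(in_2) && !any(in_1)) singletons <- c(singletons, names(fam)[in_2])
  }
  sort(unique(singletons))
}
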