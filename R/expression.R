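# Expression analysis: RPKM normalization, Pearson/complete-linkage
# hierarchical clustering, tissue-preference calls and qPCR 2^-ddCt
# relative quantification with regulation calls.

#' RPKM normalization of a count matrix
#'
#' `RPKM = count * 1e9 / (gene_length_bp * library_size)` (reads per
#' kilobase of transcript per million mapped reads).
#'
#' @param counts Numeric gene x condition matrix of read counts
#'   (non-negative), with row and column names.
#' @param gene_lengths Named numeric vector of transcript lengths in bp
#'   (> 0), covering all rows of `counts`.
#' @param library_sizes Named numeric vector of total mapped reads per
#'   condition (> 0), covering all columns of `counts`.
#' @return Matrix of RPKM values with the same dimnames as `counts`.
#' @examples
#' rpkm_normalize(matrix(10, 1, 1, dimnames = list("g", "t")),
#'                c(g = 1000), c(t = 1e6))  # 10
#' @export
rpkm_normalize <- function(counts, gene_lengths, library_sizes) {
  if (any(counts < 0)) stop("negative count")
  gl <- gene_lengths[rownames(counts)]
  ls <- library_sizes[colnames(counts)]
  if (any(is.na(gl)) || any(gl <= 0)) stop("missing or non-positive gene length")
  if (any(is.na(ls)) || any(ls <= 0)) stop("missing or non-positive library size")
  counts * 1e9 / outer(as.numeric(gl), as.numeric(ls))
}

#' Pearson-correlation distance between gene expression profiles
#'
#' `d = 1 - r` (Pearson). Genes with a constant profile have an undefined
#' correlation; they are assigned distance 1 to every other gene, with a
#' warning.
#'
#' @param matrix Numeric gene x condition matrix.
#' @return A `dist` object over genes.
#' @export
correlation_distance <- function(matrix) {
  sds <- apply(matrix, 1L, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    warning("constant expression profile(s): ",
            paste(rownames(matrix)[const], collapse = ", "),
            "; assigned distance 1 to all other genes")
  }
  r <- suppressWarnings(stats::cor(t(matrix)))
  d <- 1 - r
  d[is.na(d)] <- 1
  diag(d) <- 0
  stats::as.dist(d)
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering with Pearson-correlation distance (`1 - r`) and
#' complete linkage, the combination conventionally used for tissue
#' expression heat maps. Leaf order is made deterministic by ordering each
#' merge's subtrees (tightest first, ties by label).
#'
#' @param matrix Numeric gene x condition matrix (>= 2 genes, >= 2
#'   conditions).
#' @return An [stats::hclust] object.
#' @export
cluster_genes <- function(matrix) {
  if (nrow(matrix) < 2L || ncol(matrix) < 2L) {
    stop("clustering needs at least 2 genes and 2 conditions")
  }
  m <- matrix[order(rownames(matrix)), , drop = FALSE]
  stats::hclust(correlation_distance(m), method = "complete")
}

#' Tissue-preference calls from an expression matrix
#'
#' For each gene, the condition with the largest value (ties broken
#' alphabetically by condition label). A gene is flagged `single_tissue`
#' when its top condition exceeds `dominance_ratio` times the second
#' largest value. All-zero genes are labelled `"not detected"`.
#'
#' @param matrix Numeric gene x condition matrix (e.g. RPKM).
#' @param dominance_ratio Fold dominance required for the single-tissue
#'   flag (default 2).
#' @return Data frame with columns `gene`, `preferred`, `single_tissue`.
#' @export
tissue_preference <- function(matrix, dominance_ratio = 2) {
  conds <- colnames(matrix)
  ord <- order(conds)
  rows <- lapply(rownames(matrix), function(g) {
    v <- matrix[g, ]
    if (all(v == 0)) {
      return(data.frame(gene = g, preferred = "not detected",
                        single_tissue = FALSE, stringsAsFactors = FALSE))
    }
    v_sorted <- v[ord]  # alphabetical tie-break: first max wins
    top_idx <- which.max(v_sorted)
    top <- v_sorted[top_idx]
    second <- if (length(v_sorted) > 1L) max(v_sorted[-top_idx]) else 0
    data.frame(gene = g, preferred = names(v_sorted)[top_idx],
               single_tissue = top > dominance_ratio * second,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.mean_ct <- function(x, what) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("missing ", what, " CT values")
  mean(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = mean(Ct_target) - mean(Ct_reference)` per sample;
#' `ddCt = dCt_treatment - dCt_control`; fold change `= 2^(-ddCt)`. The
#' untreated control evaluates to exactly 1 by construction.
#'
#' @param ct_target_treat,ct_reference_treat Replicate CT values of target
#'   and reference gene in the treatment sample.
#' @param ct_target_control,ct_reference_control The same for the 0-h
#'   control sample.
#' @return Fold change (dimensionless, > 0).
#' @examples
#' relative_expression_ddct(20, 15, 21, 15)  # 2
#' @export
relative_expression_ddct <- function(ct_target_treat, ct_reference_treat,
                                     ct_target_control, ct_reference_control) {
  dct_treat <- .mean_ct(ct_target_treat, "treatment target") -
    .mean_ct(ct_reference_treat, "treatment reference")
  dct_control <- .mean_ct(ct_target_control, "control target") -
    .mean_ct(ct_reference_control, "control reference")
  2^(-(dct_treat - dct_control))
}

#' Fold-change series from a long-format CT table
#'
#' Computes per-gene, per-timepoint 2^-ddCt fold changes relative to the
#' control timepoint.
#'
#' @param ct_table Data frame with columns `gene`, `timepoint`,
#'   `replicate`, `ct_target`, `ct_reference` (as written by
#'   [generate_qpcr_ct()]).
#' @param control_time Timepoint serving as untreated control (default 0).
#' @return Data frame with columns `gene`, `timepoint`, `fold`; the control
#'   timepoint is included with fold 1.
#' @export
ddct_fold_table <- function(ct_table, control_time = 0) {
  need <- c("gene", "timepoint", "replicate", "ct_target", "ct_reference")
  missing <- setdiff(need, names(ct_table))
  if (length(missing) > 0L) {
    stop("CT table lacks column(s): ", paste(missing, collapse = ", "))
  }
  rows <- list()
  for (g in unique(ct_table$gene)) {
    sub <- ct_table[ct_table$gene == g, , drop = FALSE]
    ctrl <- sub[sub$timepoint == control_time, , drop = FALSE]
    if (nrow(ctrl) == 0L) stop("gene '", g, "' has no control timepoint")
    for (tp in sort(unique(sub$timepoint))) {
      tr <- sub[sub$timepoint == tp, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, timepoint = tp,
        fold = relative_expression_ddct(tr$ct_target, tr$ct_reference,
                                        ctrl$ct_target, ctrl$ct_reference),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Regulation call for a fold-change time series
#'
#' `down` when every fold is below `down_threshold`; `up` when some fold
#' exceeds `up_threshold` and none is below `down_threshold`; `unchanged`
#' when all folds lie within `[down_threshold, up_threshold]`; otherwise
#' `mixed`.
#'
#' @param folds Numeric vector of fold changes at the treated timepoints
#'   (control excluded), length >= 1.
#' @param down_threshold Downregulation boundary (default 0.5; a fold of
#'   exactly 0.5 is not "down").
#' @param up_threshold Upregulation boundary (default 2).
#' @return One of `"up"`, `"down"`, `"mixed"`, `"unchanged"`.
#' @export
regulation_call <- function(folds, down_threshold = 0.5, up_threshold = 2) {
  stopifnot(length(folds) >= 1L)
  any_down <- any(folds < down_threshold)
  any_up <- any(folds > up_threshold)
  if (all(folds < down_threshold)) return("down")
  if (any_up && !any_down) return("up")
  if (!any_up && !any_down) return("unchanged")
  "mixed"
}
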