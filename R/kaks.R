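# Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor multiple-hit
# correction, codon-alignment back-threading, Ks-based duplication dating
# and selection classification.
#
# Conventions: synonymous-site fractions exclude mutations to stop codons
# from both numerator and denominator; multi-hit codons are averaged over
# all mutational pathways with equal weight, excluding pathways through a
# stop codon (falling back to all pathways if every one is blocked); codon
# columns containing gaps, ambiguity codes or stop codons are excluded from
# site and difference counts.

.ng86_env <- new.env(parent = emptyenv())

.ng86_tables <- function() {
  if (!is.null(.ng86_env$sd_mat)) return(.ng86_env)
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  aa <- unname(gc_tab)
  is_stop <- aa == "*"
  nts <- c("A", "C", "G", "T")

  # per-codon synonymous site counts
  syn_sites <- numeric(length(codons))
  names(syn_sites) <- codons
  for (ci in seq_along(codons)) {
    if (is_stop[ci]) next
    cvec <- strsplit(codons[ci], "")[[1L]]
    s <- 0
    for (pos in 1:3) {
      n_syn <- 0L
      n_valid <- 0L
      for (nt in setdiff(nts, cvec[pos])) {
        mut <- cvec
        mut[pos] <- nt
        mut_cod <- paste(mut, collapse = "")
        if (gc_tab[[mut_cod]] == "*") next
        n_valid <- n_valid + 1L
        if (gc_tab[[mut_cod]] == aa[ci]) n_syn <- n_syn + 1L
      }
      if (n_valid > 0L) s <- s + n_syn / n_valid
    }
    syn_sites[ci] <- s
  }

  # pathway-averaged synonymous / nonsynonymous difference counts
  n <- length(codons)
  sd_mat <- matrix(0, n, n, dimnames = list(codons, codons))
  nd_mat <- matrix(0, n, n, dimnames = list(codons, codons))
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_len(n)) {
    if (is_stop[i]) next
    ci <- strsplit(codons[i], "")[[1L]]
    for (j in seq_len(n)) {
      if (j <= i || is_stop[j]) next
      cj <- strsplit(codons[j], "")[[1L]]
      diff_pos <- which(ci != cj)
      k <- length(diff_pos)
      if (k == 0L) next
      path_syn <- numeric(0)
      path_non <- numeric(0)
      blocked_syn <- numeric(0)
      blocked_non <- numeric(0)
      for (perm in perms[[as.character(k)]]) {
        cur <- ci
        sds <- 0L; nds <- 0L; via_stop <- FALSE
        for (p in diff_pos[perm]) {
          nxt <- cur
          nxt[p] <- cj[p]
          aa_cur <- gc_tab[[paste(cur, collapse = "")]]
          aa_nxt <- gc_tab[[paste(nxt, collapse = "")]]
          if (aa_nxt == "*" || aa_cur == "*") via_stop <- TRUE
          if (aa_cur == aa_nxt) sds <- sds + 1L else nds <- nds + 1L
          cur <- nxt
        }
        if (via_stop) {
          blocked_syn <- c(blocked_syn, sds)
          blocked_non <- c(blocked_non, nds)
        } else {
          path_syn <- c(path_syn, sds)
          path_non <- c(path_non, nds)
        }
      }
      if (length(path_syn) == 0L) {  # all pathways pass through a stop
        path_syn <- blocked_syn
        path_non <- blocked_non
      }
      sd_mat[i, j] <- sd_mat[j, i] <- mean(path_syn)
      nd_mat[i, j] <- nd_mat[j, i] <- mean(path_non)
    }
  }
  .ng86_env$codons <- codons
  .ng86_env$is_stop <- stats::setNames(is_stop, codons)
  .ng86_env$syn_sites <- syn_sites
  .ng86_env$sd_mat <- sd_mat
  .ng86_env$nd_mat <- nd_mat
  .ng86_env
}

.split_codons <- function(s) {
  if (nchar(s) %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
}

#' Construct a codon alignment
#'
#' Two equal-length gapped codon strings; gaps must occur in whole-codon
#' triplets (`---`).
#'
#' @param seq_a,seq_b Gapped coding sequences (characters `ACGT-`).
#' @return Object of class `codon_alignment` with fields `seq_a`, `seq_b`
#'   and `n_codons` (aligned codon columns with no gap in either sequence).
#' @export
codon_alignment <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences differ in length (", nchar(seq_a), " vs ",
         nchar(seq_b), ")")
  }
  ca <- .split_codons(seq_a)
  cb <- .split_codons(seq_b)
  for (cod in c(ca, cb)) {
    if (grepl("-", cod) && cod != "---") {
      stop("gaps must occur in whole-codon triplets; found '", cod, "'")
    }
  }
  structure(list(seq_a = seq_a, seq_b = seq_b,
                 n_codons = sum(ca != "---" & cb != "---")),
            class = "codon_alignment")
}

#' Back-thread a protein alignment onto coding sequences
#'
#' Converts an aligned protein pair plus the corresponding (ungapped) CDSs
#' into a codon alignment: each aligned residue is replaced by its codon and
#' each protein gap by `---`. The ungapped proteins must equal the CDS
#' translations (trailing stop trimmed).
#'
#' @param protein_aln_a,protein_aln_b Aligned (gapped) protein strings.
#' @param cds_a,cds_b DNA [seq_record()]s or character strings.
#' @return A [codon_alignment()].
#' @export
backthread_codon_alignment <- function(protein_aln_a, protein_aln_b,
                                       cds_a, cds_b) {
  thread_one <- function(aln, cds, label) {
    s <- if (inherits(cds, "seq_record")) cds$sequence else toupper(cds)
    if (nchar(s) %% 3L == 0L) {
      tail_cod <- substring(s, nchar(s) - 2L, nchar(s))
      if (Biostrings::GENETIC_CODE[[tail_cod]] == "*") {
        s <- substr(s, 1L, nchar(s) - 3L)
      }
    }
    prot <- translate_cds(s, trim_stop = FALSE)
    ungapped <- gsub("-", "", aln)
    if (nchar(ungapped) != nchar(prot)) {
      stop("protein/CDS length mismatch for ", label, ": ", nchar(ungapped),
           " aa vs ", nchar(prot), " aa translated")
    }
    pa <- strsplit(ungapped, "")[[1L]]
    pt <- strsplit(prot, "")[[1L]]
    mism <- which(pa != pt)
    if (length(mism) > 0L) {
      stop("protein does not match CDS translation for ", label,
           ": residue ", mism[1L], " is '", pa[mism[1L]],
           "' but translation has '", pt[mism[1L]], "'")
    }
    codons <- .split_codons(s)
    out <- character(nchar(aln))
    k <- 0L
    chars <- strsplit(aln, "")[[1L]]
    for (i in seq_along(chars)) {
      if (chars[i] == "-") {
        out[i] <- "---"
      } else {
        k <- k + 1L
        out[i] <- codons[k]
      }
    }
    paste(out, collapse = "")
  }
  codon_alignment(thread_one(protein_aln_a, cds_a, "sequence a"),
                  thread_one(protein_aln_b, cds_b, "sequence b"))
}

#' Jukes-Cantor multiple-hit correction
#' @param p Proportion of observed differences (must be < 3/4).
#' @return Corrected distance `-(3/4) ln(1 - 4p/3)`.
#' @export
jc_correct <- function(p) {
  if (any(p >= 3 / 4)) {
    stop("correction undefined: observed proportion >= 3/4")
  }
  -(3 / 4) * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) Ka and Ks for a codon alignment
#'
#' Computes average synonymous (S) and nonsynonymous (N) site counts over
#' both sequences, pathway-averaged synonymous/nonsynonymous difference
#' counts, and Jukes-Cantor-corrected rates.
#'
#' @param aln A [codon_alignment()].
#' @return List with `ka`, `ks`, `s_sites`, `n_sites`, `sd`, `nd`, `ps`,
#'   `pn` and `n_codons` (codon columns actually counted).
#' @examples
#' aln <- codon_alignment(strrep("TTT", 9),
#'                        paste0("TTC", strrep("TTT", 8)))
#' ng86_kaks(aln)$ks  # 0.4408...
#' @export
ng86_kaks <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  tab <- .ng86_tables()
  ca <- .split_codons(aln$seq_a)
  cb <- .split_codons(aln$seq_b)
  usable <- ca %in% tab$codons & cb %in% tab$codons &
    !is.na(tab$is_stop[ca]) & !is.na(tab$is_stop[cb])
  usable[usable] <- !tab$is_stop[ca[usable]] & !tab$is_stop[cb[usable]]
  ca <- ca[usable]; cb <- cb[usable]
  if (length(ca) == 0L) stop("no ungapped, stop-free codon columns to count")
  s_sites <- (sum(tab$syn_sites[ca]) + sum(tab$syn_sites[cb])) / 2
  n_sites <- 3 * length(ca) - s_sites
  idx <- cbind(match(ca, tab$codons), match(cb, tab$codons))
  sd <- sum(tab$sd_mat[idx])
  nd <- sum(tab$nd_mat[idx])
  ps <- sd / s_sites
  pn <- nd / n_sites
  list(ka = jc_correct(pn), ks = jc_correct(ps),
       s_sites = s_sites, n_sites = n_sites, sd = sd, nd = nd,
       ps = ps, pn = pn, n_codons = length(ca))
}

#' Date a duplication event from Ks
#'
#' Uses the soybean synonymous divergence rate `lambda` (substitutions per
#' synonymous site per year): `T = Ks / (2 * lambda) * 1e-6` million years.
#'
#' @param ks Synonymous substitutions per synonymous site (>= 0).
#' @param lambda Synonymous rate per site per year (default 6.1e-9).
#' @return Divergence time(s) in million years (unrounded; the conventional
#'   reporting precision is two decimals).
#' @examples
#' round(divergence_time(0.0802), 2)  # 6.57
#' @export
divergence_time <- function(ks, lambda = 6.1e-9) {
  if (any(ks < 0)) stop("negative Ks")
  ks / (2 * lambda) * 1e-6
}

#' Classify selection from a Ka/Ks ratio
#'
#' Ratios below 1 indicate purifying (negative) selection, ratios above 1
#' positive selection, and ratios equal to 1 (within `tol`) neutral drift.
#'
#' @param ratio Ka/Ks ratio(s) (>= 0).
#' @param tol Equality tolerance for the neutral boundary (default 1e-9).
#' @return Character vector: `"purifying"`, `"neutral"` or `"positive"`.
#' @export
classify_selection <- function(ratio, tol = 1e-9) {
  if (any(ratio < 0)) stop("negative Ka/Ks ratio")
  ifelse(abs(ratio - 1) <= tol, "neutral",
         ifelse(ratio < 1, "purifying", "positive"))
}

#' Global protein alignment of two sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps) via
#' [Biostrings::pairwiseAlignment()]; used to prepare pairwise codon
#' alignments for Ka/Ks estimation.
#'
#' @param protein_a,protein_b Protein [seq_record()]s or strings.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return List with gapped strings `aln_a`, `aln_b` and the alignment
#'   `score`.
#' @export
align_proteins_global <- function(protein_a, protein_b,
                                  gap_opening = 10, gap_extension = 0.5) {
  sa <- if (inherits(protein_a, "seq_record")) protein_a$sequence else protein_a
  sb <- if (inherits(protein_b, "seq_record")) protein_b$sequence else protein_b
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  list(aln_a = as.character(Biostrings::alignedPattern(pa)),
       aln_b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Ka/Ks analysis of one gene pair from protein and CDS sequences
#'
#' Aligns the proteins globally, back-threads the codon alignment, estimates
#' Ka/Ks by NG86 and dates the duplication from Ks.
#'
#' @param protein_a,protein_b Protein [seq_record()]s.
#' @param cds_a,cds_b Matching CDS [seq_record()]s.
#' @param lambda Synonymous rate per site per year for dating.
#' @return List of class `kaks_result`: `ka`, `ks`, `ratio`, `time_mya`,
#'   `selection_class` plus the NG86 site/difference counts.
#' @export
kaks_pair <- function(protein_a, protein_b, cds_a, cds_b, lambda = 6.1e-9) {
  aln <- align_proteins_global(protein_a, protein_b)
  caln <- backthread_codon_alignment(aln$aln_a, aln$aln_b, cds_a, cds_b)
  est <- ng86_kaks(caln)
  ratio <- if (est$ks > 0) est$ka / est$ks else NA_real_
  structure(c(est,
              list(ratio = ratio,
                   time_mya = divergence_time(est$ks, lambda),
                   selection_class = if (is.na(ratio)) NA_character_ else
                     classify_selection(ratio))),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result: Ka=%.4f Ks=%.4f Ka/Ks=%s T=%.2f My (%s)>\n",
              x$ka, x$ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.4f", x$ratio),
              x$time_mya,
              if (is.na(x$selection_class)) "NA" else x$selection_class))
  invisible(x)
}
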