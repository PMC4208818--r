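# Intron-phase analysis and paralog structure comparison.
#
# Intron phase is defined relative to the coding sequence only: phase 0
# introns fall exactly between two codons, phase 1 after the first
# nucleotide of a codon, phase 2 after the second. The family hallmark is a
# phase-0 intron between codons 16 and 17 of the IQ67 domain.

#' Intron phases of a gene model
#'
#' One record per intron between consecutive CDS segments, in transcription
#' order. `cds_offset` is the number of coding nucleotides upstream of the
#' intron; `phase = cds_offset mod 3`; `interrupted_codon` is the codon the
#' intron falls after (phase 0) or within (phase 1/2).
#'
#' @param gene A [gene_model()] whose total CDS length is divisible by 3.
#' @return Data frame with columns `index`, `cds_offset`, `phase`,
#'   `interrupted_codon`; zero rows for an intronless CDS.
#' @examples
#' g <- gene_model("g", "chr1", "+", cbind(c(0L, 148L), c(48L, 208L)))
#' intron_phases(g)  # one phase-0 intron after codon 16
#' @export
intron_phases <- function(gene) {
  cd <- gene$cds_segments
  total <- cds_length(gene)
  if (total %% 3L != 0L) {
    stop("total CDS length of gene '", gene$gene_id, "' (", total,
         " nt) is not divisible by 3")
  }
  if (nrow(cd) < 2L) {
    return(data.frame(index = integer(0), cds_offset = integer(0),
                      phase = integer(0), interrupted_codon = integer(0)))
  }
  ord <- if (gene$strand == "+") seq_len(nrow(cd)) else rev(seq_len(nrow(cd)))
  lens <- cd[ord, 2L] - cd[ord, 1L]
  offsets <- cumsum(lens)[-length(lens)]
  phase <- offsets %% 3L
  interrupted <- ifelse(phase == 0L, offsets %/% 3L,
                        as.integer(ceiling(offsets / 3)))
  data.frame(index = seq_along(offsets),
             cds_offset = as.integer(offsets),
             phase = as.integer(phase),
             interrupted_codon = as.integer(interrupted))
}

#' Test for the conserved IQ67-domain phase-0 intron
#'
#' `TRUE` iff some intron of the gene has phase 0 and falls exactly after
#' codon 16 of the IQ67 domain, i.e. at coding offset
#' `3 * (domain_start_codon - 1 + 16)` where `domain_start_codon` is the
#' protein position of the domain's first residue.
#'
#' @param gene A [gene_model()].
#' @param domain An `iq67_domain` (from [call_iq67_domains()]) called on the
#'   gene's translated CDS, or a list with a `start` field.
#' @return Logical scalar.
#' @export
has_conserved_iq67_intron <- function(gene, domain) {
  n_codons <- cds_length(gene) %/% 3L
  dom_start <- domain$start
  if (dom_start < 1L || dom_start + 66L > n_codons) {
    stop("IQ67 domain (", dom_start, "-", dom_start + 66L,
         ") lies outside the translation of gene '", gene$gene_id,
         "' (", n_codons, " codons)")
  }
  target_offset <- 3L * (dom_start - 1L + 16L)
  ip <- intron_phases(gene)
  any(ip$phase == 0L & ip$cds_offset == target_offset)
}

#' Compare the exon/intron structure of a paralog pair
#'
#' Verdicts: `conserved` when the intron phase vectors are identical (hence
#' equal exon counts); `gain_loss_candidate` when one phase vector equals the
#' other with a single intron inserted or deleted (edit distance 1 by
#' insertion/deletion); otherwise `divergent`.
#'
#' @param a,b [gene_model()] objects.
#' @return A list of class `structure_comparison` with fields `gene_a`,
#'   `gene_b`, `exon_counts`, `phase_vectors` and `verdict`.
#' @export
compare_pair_structures <- function(a, b) {
  pa <- intron_phases(a)$phase
  pb <- intron_phases(b)$phase
  verdict <- if (length(pa) == length(pb) && all(pa == pb)) {
    "conserved"
  } else if (.single_indel(pa, pb)) {
    "gain_loss_candidate"
  } else {
    "divergent"
  }
  structure(list(gene_a = a$gene_id, gene_b = b$gene_id,
                 exon_counts = c(nrow(a$cds_segments), nrow(b$cds_segments)),
                 phase_vectors = list(pa, pb),
                 verdict = verdict),
            class = "structure_comparison")
}

# TRUE when the shorter vector equals the longer with one element removed.
.single_indel <- function(x, y) {
  if (abs(length(x) - length(y)) != 1L) return(FALSE)
  long <- if (length(x) > length(y)) x else y
  short <- if (length(x) > length(y)) y else x
  for (drop in seq_along(long)) {
    if (identical(long[-drop], short)) return(TRUE)
  }
  FALSE
}

#' @export
print.structure_comparison <- function(x, ...) {
  cat(sprintf("<structure_comparison %s vs %s: %s (phases %s | %s)>\n",
              x$gene_a, x$gene_b, x$verdict,
              paste(x$phase_vectors[[1L]], collapse = ","),
              paste(x$phase_vectors[[2L]], collapse = ",")))
  invisible(x)
}
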