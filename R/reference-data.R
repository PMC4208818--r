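# Accessors for the published soybean GmIQD reference tables shipped with
# the package: the 31 paralogous pairs with their Ka/Ks/dating estimates,
# and the 67-gene locus table (coordinates, ORF and protein descriptors).

#' Published divergence estimates for the 31 GmIQD paralogous pairs
#'
#' Ka, Ks, Ka/Ks, duplication date (million years, from the soybean
#' synonymous rate 6.1e-9/site/year) and duplicate type (S = segmental,
#' O = other) for the 31 soybean IQD paralog pairs.
#'
#' @return Data frame with columns `group`, `pair_no`, `gene_a`, `gene_b`,
#'   `ka`, `ks`, `ka_ks`, `date_mya`, `duplicate_type`.
#' @export
gmiqd_paralog_divergence <- function() {
  path <- system.file("extdata", "gmiqd_paralog_divergence.tsv",
                      package = "iqdfam", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' The 67 soybean GmIQD gene loci
#'
#' Locus table for GmIQD1-67: Glyma identifier, chromosome, genomic
#' coordinates, ORF length (bp, stop codon included), protein length (aa),
#' isoelectric point, molecular weight (kDa) and exon count.
#'
#' @return Data frame with one row per gene.
#' @export
gmiqd_gene_table <- function() {
  path <- system.file("extdata", "gmiqd_gene_table.tsv",
                      package = "iqdfam", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
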