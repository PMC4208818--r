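# Shared fixtures. Simulations are cached per session so that several test
# files can reuse the same synthetic genome without regenerating it.

.fixture_cache <- new.env(parent = emptyenv())

# Small genome: quick, used by structural/unit tests.
small_sim <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- generate_family_genome(family_spec(
      n_chromosomes = 2L, chromosome_length = 2e5, n_iqd_genes = 3L,
      n_background_genes = 18L, tandem_pairs = 1L, segmental_blocks = 1L,
      seed = 11L))
  }
  .fixture_cache$small
}

# Default study-condition genome: used by the acceptance property suite.
study_sim <- function() {
  if (is.null(.fixture_cache$study)) {
    .fixture_cache$study <- generate_family_genome(family_spec(seed = 101L))
  }
  .fixture_cache$study
}

# Duplicated-block table from a simulation's truth layout.
truth_blocks <- function(sim) {
  bl <- sim$truth$block_layout
  if (length(bl) == 0L) {
    return(duplicated_block_set(data.frame(
      block_id = integer(0), chrom_a = character(0), start_a = numeric(0),
      end_a = numeric(0), chrom_b = character(0), start_b = numeric(0),
      end_b = numeric(0))))
  }
  duplicated_block_set(do.call(rbind, lapply(seq_along(bl), function(i) {
    data.frame(block_id = i,
               chrom_a = bl[[i]]$chrom_a, start_a = bl[[i]]$start_a,
               end_a = bl[[i]]$end_a,
               chrom_b = bl[[i]]$chrom_b, start_b = bl[[i]]$start_b,
               end_b = bl[[i]]$end_b, stringsAsFactors = FALSE)
  })))
}

# Minimal annotation builder: genes given as list(id, chrom, start, end)
# (0-based half-open, single exon, + strand).
toy_annotation <- function(genes, chrom_len = 1e6) {
  models <- lapply(genes, function(g) {
    gene_model(g$id, g$chrom, "+", cbind(g$start, g$end))
  })
  chroms <- unique(vapply(genes, function(g) g$chrom, character(1L)))
  annotation(models, stats::setNames(rep(chrom_len, length(chroms)), chroms))
}

# Gene model with given coding segment lengths (introns of 100 bp between
# them), on either strand.
toy_gene_lengths <- function(lengths, strand = "+", id = "g", chrom = "chr1") {
  starts <- cumsum(c(0L, head(lengths, -1L) + 100L))
  ex <- cbind(starts, starts + lengths)
  if (strand == "-") {
    total <- max(ex[, 2L])
    ex <- cbind(total - ex[, 2L], total - ex[, 1L])
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    # reversing genomic layout keeps transcription order = input order
  }
  gene_model(id, chrom, strand, ex)
}

# Hand-built synteny block for arithmetic tests.
toy_block <- function(n_pairs, n_genes_a, n_genes_b,
                      anchor_flags = c(TRUE, rep(FALSE, n_pairs - 1L))) {
  pairs <- data.frame(
    gene_a = sprintf("a%02d", seq_len(n_pairs)),
    gene_b = sprintf("b%02d", seq_len(n_pairs)),
    score = 500, is_best_non_self = !anchor_flags, reciprocal = TRUE,
    is_anchor = anchor_flags, stringsAsFactors = FALSE)
  structure(list(anchor_pair = c("a01", "b01"),
                 segment_a = list(chrom = "c1", start = 0, end = 2e5),
                 segment_b = list(chrom = "c2", start = 0, end = 2e5),
                 genes_a = sprintf("a%02d", seq_len(n_genes_a)),
                 genes_b = sprintf("b%02d", seq_len(n_genes_b)),
                 conserved_pairs = pairs, orientation = "same"),
            class = "synteny_block")
}

random_protein_string <- function(n, alphabet = c("A", "R", "N", "D", "C",
                                                  "E", "G", "H", "I", "L",
                                                  "K", "M", "F", "P", "S",
                                                  "T", "W", "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
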