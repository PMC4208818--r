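# Synthetic genomes, gene families, duplicates, expression matrices and
# qPCR CT tables with known ground truth, so that every downstream stage of
# the pipeline can be tested without genome downloads.
#
# The IQ67 domains implanted by the generator follow a single canonical
# 67-residue template: a strict IQ motif at domain positions 1-11, 11
# intervening residues carrying one 1-5-10 motif, a second IQ at 23-33, 15
# intervening residues carrying one 1-8-14 motif, a third IQ at 49-59, and
# an 8-residue tail. Each IQD gene carries a phase-0 intron between domain
# codons 16 and 17, the family's diagnostic exon-intron boundary.

#' The canonical 67-residue IQ67 domain template
#'
#' Three strict IQ motifs (`IQAAARGAAAR`) at the canonical 11/15
#' intervening-residue spacing, with one 1-5-10 and one 1-8-14 motif
#' embedded in the spacers.
#'
#' @return A 67-character protein string.
#' @export
canonical_iq67_template <- function() {
  iq <- "IQAAARGAAAR"
  paste0(iq,
         "FAAAIAAAAW", "A",            # 11 spacer residues with a 1-5-10
         iq,
         "FAAAAAAFAAAAAW", "A",        # 15 spacer residues with a 1-8-14
         iq,
         "AAAAAAAA")                   # tail to 67
}

# Flank alphabet deliberately excludes Q so that implanted domains are the
# only relaxed-IQ anchors in a generated protein.
.FLANK_AA <- c("A", "D", "E", "G", "K", "N", "P", "R", "S", "T", "H", "F",
               "L", "V", "I", "W", "M", "C", "Y")

# Fixed codon-usage weights: mild AT3 bias typical of plant genomes; stop
# codons excluded.
.codon_usage <- function() {
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  w <- ifelse(substring(sense, 3L, 3L) %in% c("A", "T"), 2, 1)
  stats::setNames(w, sense)
}

.random_protein <- function(n_aa) {
  paste(sample(.FLANK_AA, n_aa, replace = TRUE), collapse = "")
}

# Reverse-translate a protein using the fixed codon-usage table; appends a
# stop codon when `add_stop`.
.reverse_translate <- function(protein, add_stop = TRUE) {
  usage <- .codon_usage()
  gc_tab <- Biostrings::GENETIC_CODE
  by_aa <- split(names(usage), gc_tab[names(usage)])
  aa <- strsplit(protein, "")[[1L]]
  codons <- vapply(aa, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue '", a, "'")
    if (length(opts) == 1L) opts else {
      sample(opts, 1L, prob = usage[opts])
    }
  }, character(1L))
  stop_cod <- if (add_stop) sample(c("TAA", "TGA", "TAG"), 1L) else character(0)
  paste(c(codons, stop_cod), collapse = "")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
}

.random_intron <- function() {
  paste0("GT", .random_dna(sample(96:396, 1L)), "AG")
}

#' Family specification for the synthetic genome generator
#'
#' Defaults are scaled-down but realistic study conditions: a handful of
#' chromosomes, IQD genes embedded among background genes, one tandem pair
#' and two segmentally duplicated blocks, with duplicate divergence in the
#' range observed for recent plant paralog pairs.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Chromosome length in bp.
#' @param n_iqd_genes Number of primary IQD genes (tandem/segmental copies
#'   are generated in addition).
#' @param n_background_genes Number of non-family background genes.
#' @param tandem_pairs Number of IQD tandem pairs to implant.
#' @param segmental_blocks Number of segmentally duplicated blocks, each
#'   carrying one IQD gene and `flank_genes_per_block` collinear background
#'   genes on each side of the duplication.
#' @param flank_genes_per_block Background genes flanking each block anchor
#'   (>= 5 for the large-scale duplication rule to be satisfiable).
#' @param ka_target,ks_target Target NG86 divergence of implanted duplicate
#'   pairs (substitutions/site); `ks_target` must be < 0.7.
#' @param intron_plan Optional list of `(codon_index, phase)` pairs applied
#'   to every IQD gene *in addition to* the diagnostic phase-0 intron
#'   between IQ67-domain codons 16 and 17; positions are CDS codon indices.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_chromosomes = 5L, chromosome_length = 5e5,
                        n_iqd_genes = 8L, n_background_genes = 60L,
                        tandem_pairs = 1L, segmental_blocks = 2L,
                        flank_genes_per_block = 6L,
                        ka_target = 0.03, ks_target = 0.12,
                        intron_plan = NULL, seed = 1L) {
  stopifnot(n_chromosomes >= 1L, n_iqd_genes >= 0L, n_background_genes >= 0L,
            tandem_pairs >= 0L, segmental_blocks >= 0L,
            ka_target >= 0, ks_target >= 0)
  if (ks_target >= 0.7) {
    stop("ks_target must be < 0.7 (Jukes-Cantor correction undefined region)")
  }
  if (tandem_pairs + segmental_blocks > n_iqd_genes) {
    stop("tandem_pairs + segmental_blocks cannot exceed n_iqd_genes")
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = chromosome_length,
                 n_iqd_genes = as.integer(n_iqd_genes),
                 n_background_genes = as.integer(n_background_genes),
                 tandem_pairs = as.integer(tandem_pairs),
                 segmental_blocks = as.integer(segmental_blocks),
                 flank_genes_per_block = as.integer(flank_genes_per_block),
                 ka_target = ka_target, ks_target = ks_target,
                 intron_plan = intron_plan, seed = as.integer(seed)),
            class = "family_spec")
}

#' Mutate a coding sequence toward target Ka/Ks divergence
#'
#' Applies point substitutions only (no indels, no stop codons introduced,
#' at most one substitution per codon) so that NG86 estimates on the
#' original/mutant pair are close to the targets in expectation: the number
#' of synonymous (nonsynonymous) substitutions is the NG86 site count times
#' the Jukes-Cantor-inverted target proportion.
#'
#' @param cds A DNA [seq_record()] or string; length divisible by 3, no
#'   internal stop codons (a trailing stop codon is left untouched).
#' @param ka_target,ks_target Target substitutions per site; `ks_target`
#'   must be < 0.7.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param protect_codons Codon indices where nonsynonymous substitutions
#'   are disallowed (synonymous ones remain possible). Used to keep
#'   implanted IQ67 domains intact in duplicated family genes, mirroring
#'   the purifying selection acting on the domain.
#' @return The mutated CDS as a [seq_record()] (id suffixed `_mut`).
#' @export
mutate_codon_sequence <- function(cds, ka_target, ks_target, seed = NULL,
                                  protect_codons = integer(0)) {
  if (ks_target >= 0.7) {
    stop("ks_target must be < 0.7 (correction undefined region)")
  }
  stopifnot(ka_target >= 0, ks_target >= 0)
  if (!is.null(seed)) set.seed(seed)
  id <- if (inherits(cds, "seq_record")) cds$id else "cds"
  s <- if (inherits(cds, "seq_record")) cds$sequence else toupper(cds)
  if (nchar(s) %% 3L != 0L) stop("CDS length not divisible by 3")
  codons <- .split_codons(s)
  tab <- .ng86_tables()
  gc_tab <- Biostrings::GENETIC_CODE
  is_stop <- gc_tab[codons] == "*"
  if (any(is_stop[-length(codons)])) stop("internal stop codon in CDS")
  sense_idx <- which(!is_stop)

  if (ka_target == 0 && ks_target == 0) {
    return(seq_record(paste0(id, "_mut"), s, "dna"))
  }

  s_sites <- sum(tab$syn_sites[codons[sense_idx]])
  n_sites <- 3 * length(sense_idx) - s_sites
  p_from_d <- function(d) (3 / 4) * (1 - exp(-4 * d / 3))
  k_syn <- round(s_sites * p_from_d(ks_target))
  k_non <- round(n_sites * p_from_d(ka_target))
  if (k_syn + k_non > length(sense_idx)) {
    stop("requested divergence needs more substitutions (", k_syn + k_non,
         ") than codons available (", length(sense_idx), ")")
  }

  # single-substitution options per codon, classified syn/nonsyn, no stops
  options_for <- function(cod, synonymous) {
    cvec <- strsplit(cod, "")[[1L]]
    out <- character(0)
    for (pos in 1:3) {
      for (nt in setdiff(c("A", "C", "G", "T"), cvec[pos])) {
        mut <- cvec; mut[pos] <- nt
        mc <- paste(mut, collapse = "")
        if (gc_tab[[mc]] == "*") next
        if ((gc_tab[[mc]] == gc_tab[[cod]]) == synonymous) out <- c(out, mc)
      }
    }
    out
  }
  draw <- function(x, n) x[sample.int(length(x), n)]
  can_syn <- sense_idx[vapply(codons[sense_idx],
                              function(c) length(options_for(c, TRUE)) > 0,
                              logical(1L))]
  if (k_syn > length(can_syn)) {
    stop("not enough synonymously mutable codons for the requested divergence")
  }
  pick_syn <- if (k_syn > 0) draw(can_syn, k_syn) else integer(0)
  remaining <- setdiff(setdiff(sense_idx, pick_syn), protect_codons)
  can_non <- remaining[vapply(codons[remaining],
                              function(c) length(options_for(c, FALSE)) > 0,
                              logical(1L))]
  if (k_non > length(can_non)) {
    stop("not enough nonsynonymously mutable codons for the requested divergence")
  }
  pick_non <- if (k_non > 0) draw(can_non, k_non) else integer(0)
  for (i in pick_syn) {
    opts <- options_for(codons[i], TRUE)
    codons[i] <- if (length(opts) == 1L) opts else sample(opts, 1L)
  }
  for (i in pick_non) {
    opts <- options_for(codons[i], FALSE)
    codons[i] <- if (length(opts) == 1L) opts else sample(opts, 1L)
  }
  seq_record(paste0(id, "_mut"), paste(codons, collapse = ""), "dna")
}

# --- gene assembly helpers -------------------------------------------------

# Build the genomic structure of a gene from its CDS (stop included) and a
# vector of intron coding offsets (nt of CDS upstream of each intron).
# Returns list(tx_seq, exon_local, cds_local) in transcription orientation,
# intervals 0-based half-open relative to the gene's transcribed span.
.build_gene_structure <- function(cds_seq, intron_offsets) {
  intron_offsets <- sort(unique(intron_offsets))
  L <- nchar(cds_seq)
  if (any(intron_offsets <= 0L | intron_offsets >= L)) {
    stop("intron offsets must lie strictly inside the CDS")
  }
  bounds <- c(0L, intron_offsets, L)
  pieces <- character(0)
  exon_local <- NULL
  cursor <- 0L
  for (k in seq_len(length(bounds) - 1L)) {
    ex_seq <- substr(cds_seq, bounds[k] + 1L, bounds[k + 1L])
    pieces <- c(pieces, ex_seq)
    exon_local <- rbind(exon_local, c(cursor, cursor + nchar(ex_seq)))
    cursor <- cursor + nchar(ex_seq)
    if (k < length(bounds) - 1L) {
      intr <- .random_intron()
      pieces <- c(pieces, intr)
      cursor <- cursor + nchar(intr)
    }
  }
  list(tx_seq = paste(pieces, collapse = ""), exon_local = exon_local)
}

# Convert intron_plan entries (codon_index, phase) to coding offsets.
.plan_to_offsets <- function(plan) {
  vapply(plan, function(p) {
    codon <- as.integer(p[[1L]]); phase <- as.integer(p[[2L]])
    if (!phase %in% 0:2) stop("intron phase must be 0, 1 or 2")
    if (phase == 0L) 3L * codon else 3L * (codon - 1L) + phase
  }, integer(1L))
}

#' Generate a synthetic genome with an implanted IQD gene family
#'
#' Lays out IQD genes (each encoding the canonical IQ67 domain and carrying
#' the diagnostic phase-0 intron between domain codons 16 and 17), tandem
#' duplicate pairs, segmentally duplicated blocks with collinear flanking
#' genes, and background genes across the chromosomes, and returns the
#' genome sequences, the annotation and a truth table describing every
#' implanted feature.
#'
#' @param spec A [family_spec()].
#' @return List with components `genome` (named list of chromosome
#'   [seq_record()]s), `annotation` (an [annotation()]), `proteins` and
#'   `cds` (named lists of [seq_record()]s per gene) and `truth`, a list
#'   with `domain_locations` (gene -> c(start, end) protein coordinates),
#'   `pair_types` (data frame gene_a/gene_b/type), `pair_divergence`
#'   (gene_a/gene_b/ka_true/ks_true), `block_layout` (list of implanted
#'   blocks) and `intron_truth` (data frame gene/cds_offset/phase).
#' @export
generate_family_genome <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  template <- canonical_iq67_template()

  genes_out <- list()     # per gene: list(id, cds, protein, intron_offsets)
  truth_domains <- list()
  truth_pairs <- NULL
  truth_div <- NULL
  truth_introns <- NULL
  blocks <- list()

  extra_offsets_for <- function(n_codons) {
    if (is.null(spec$intron_plan)) integer(0) else {
      off <- .plan_to_offsets(spec$intron_plan)
      off[off < 3L * n_codons]
    }
  }

  make_iqd_gene <- function(id) {
    n_flank <- sample(30:80, 1L)
    c_flank <- sample(50:150, 1L)
    protein <- paste0(.random_protein(n_flank), template,
                      .random_protein(c_flank))
    cds <- .reverse_translate(protein)
    n_codons <- nchar(cds) %/% 3L
    diag_offset <- 3L * (n_flank + 16L)
    offsets <- sort(unique(c(diag_offset, extra_offsets_for(n_codons))))
    truth_domains[[id]] <<- c(n_flank + 1L, n_flank + 67L)
    truth_introns <<- rbind(truth_introns, data.frame(
      gene = id, cds_offset = offsets, phase = offsets %% 3L,
      stringsAsFactors = FALSE))
    list(id = id, cds = cds, protein = protein, intron_offsets = offsets)
  }

  make_background_gene <- function(id) {
    protein <- .random_protein(sample(120:380, 1L))
    cds <- .reverse_translate(protein)
    n_intr <- sample(0:2, 1L)
    offsets <- if (n_intr > 0L) {
      sort(sample(seq(3L, nchar(cds) - 3L, by = 1L), n_intr))
    } else integer(0)
    list(id = id, cds = cds, protein = protein, intron_offsets = offsets)
  }

  mutate_gene <- function(g, new_id) {
    dom <- truth_domains[[g$id]]
    protect <- if (is.null(dom)) integer(0) else seq(dom[1L], dom[2L])
    mut <- mutate_codon_sequence(g$cds, spec$ka_target, spec$ks_target,
                                 protect_codons = protect)
    list(id = new_id, cds = mut$sequence,
         protein = translate_cds(mut$sequence), intron_offsets = g$intron_offsets)
  }

  # --- compose the gene roster ---------------------------------------------
  iqd_ids <- sprintf("IQD%03d", seq_len(spec$n_iqd_genes))
  iqd_genes <- lapply(iqd_ids, make_iqd_gene)
  names(iqd_genes) <- iqd_ids

  n_bg_in_blocks <- spec$segmental_blocks * 2L * spec$flank_genes_per_block
  if (spec$n_background_genes < n_bg_in_blocks) {
    stop("n_background_genes (", spec$n_background_genes,
         ") too small for the requested segmental blocks (need ",
         n_bg_in_blocks, " flanking genes)")
  }
  bg_ids <- sprintf("BG%03d", seq_len(spec$n_background_genes))
  bg_genes <- lapply(bg_ids, make_background_gene)
  names(bg_genes) <- bg_ids

  # roster entries: list(gene, chrom_slot, group); groups are placed
  # contiguously, single genes independently
  add_pair <- function(a, b, type) {
    truth_pairs <<- rbind(truth_pairs, data.frame(
      gene_a = a, gene_b = b, type = type, stringsAsFactors = FALSE))
    truth_div <<- rbind(truth_div, data.frame(
      gene_a = a, gene_b = b, ka_true = spec$ka_target,
      ks_true = spec$ks_target, stringsAsFactors = FALSE))
  }

  # tandem pairs: IQD gene i and a mutated copy placed adjacently
  tandem_groups <- list()
  used_iqd <- 0L
  for (t in seq_len(spec$tandem_pairs)) {
    used_iqd <- used_iqd + 1L
    src <- iqd_genes[[used_iqd]]
    copy_id <- paste0(src$id, "t")
    copy <- mutate_gene(src, copy_id)
    truth_domains[[copy_id]] <- truth_domains[[src$id]]
    add_pair(src$id, copy_id, "tandem")
    tandem_groups[[t]] <- list(src, copy)
  }

  # segmental blocks: anchor IQD gene + flanking background genes, the whole
  # run duplicated onto another chromosome with every gene mutated
  seg_groups <- list()
  bg_used <- 0L
  for (b in seq_len(spec$segmental_blocks)) {
    used_iqd <- used_iqd + 1L
    anchor <- iqd_genes[[used_iqd]]
    n_side <- spec$flank_genes_per_block %/% 2L
    left <- bg_genes[bg_used + seq_len(n_side)]
    right <- bg_genes[bg_used + n_side + seq_len(spec$flank_genes_per_block - n_side)]
    bg_used <- bg_used + spec$flank_genes_per_block
    source_run <- c(left, list(anchor), right)
    copy_run <- lapply(source_run, function(g) {
      mutate_gene(g, paste0(g$id, "d"))
    })
    copy_anchor_id <- paste0(anchor$id, "d")
    truth_domains[[copy_anchor_id]] <- truth_domains[[anchor$id]]
    add_pair(anchor$id, copy_anchor_id, "segmental")
    seg_groups[[b]] <- list(source = source_run, copy = copy_run,
                            anchor = anchor$id, copy_anchor = copy_anchor_id)
  }

  singles <- c(iqd_genes[setdiff(seq_len(spec$n_iqd_genes),
                                 seq_len(used_iqd))],
               bg_genes[setdiff(seq_len(spec$n_background_genes),
                                seq_len(bg_used))])

  # --- layout ---------------------------------------------------------------
  chroms <- sprintf("Chr%02d", seq_len(spec$n_chromosomes))
  cursor <- stats::setNames(rep(5000, spec$n_chromosomes), chroms)
  placements <- list()  # id -> list(gene, chrom, start, strand, structure)

  place_gene <- function(g, chrom, strand = sample(c("+", "-"), 1L),
                         gap = sample(2000:5000, 1L)) {
    structure_ <- .build_gene_structure(g$cds, g$intron_offsets)
    glen <- nchar(structure_$tx_seq)
    start <- cursor[[chrom]]
    if (start + glen > spec$chromosome_length) {
      stop("genes do not fit on chromosome ", chrom,
           " (length ", spec$chromosome_length, " bp)")
    }
    cursor[[chrom]] <<- start + glen + gap
    placements[[g$id]] <<- list(gene = g, chrom = chrom, start = start,
                                strand = strand, structure = structure_)
    invisible(NULL)
  }

  least_loaded <- function(exclude = character(0)) {
    cand <- setdiff(chroms, exclude)
    cand[which.min(cursor[cand])]
  }

  for (grp in tandem_groups) {
    ch <- least_loaded()
    place_gene(grp[[1L]], ch)
    place_gene(grp[[2L]], ch, gap = sample(2000:4000, 1L))
  }
  for (grp in seg_groups) {
    ch_a <- least_loaded()
    start_a <- cursor[[ch_a]]
    for (g in grp$source) place_gene(g, ch_a)
    end_a <- cursor[[ch_a]]
    ch_b <- least_loaded(exclude = ch_a)
    start_b <- cursor[[ch_b]]
    for (g in grp$copy) place_gene(g, ch_b)
    end_b <- cursor[[ch_b]]
    blocks[[length(blocks) + 1L]] <- list(
      anchor_pair = c(grp$anchor, grp$copy_anchor),
      chrom_a = ch_a, start_a = start_a, end_a = end_a,
      chrom_b = ch_b, start_b = start_b, end_b = end_b,
      genes_a = vapply(grp$source, function(g) g$id, character(1L)),
      genes_b = vapply(grp$copy, function(g) g$id, character(1L)))
  }
  for (g in singles) place_gene(g, least_loaded())

  # --- genome assembly ------------------------------------------------------
  genome <- list()
  for (ch in chroms) {
    base <- .random_dna(spec$chromosome_length)
    for (pl in placements) {
      if (pl$chrom != ch) next
      gseq <- pl$structure$tx_seq
      if (pl$strand == "-") gseq <- revcomp(gseq)
      base <- paste0(substr(base, 1L, pl$start),
                     gseq,
                     substr(base, pl$start + nchar(gseq) + 1L,
                            spec$chromosome_length))
    }
    genome[[ch]] <- seq_record(ch, base, "dna")
  }

  # --- gene models ----------------------------------------------------------
  gene_models <- list()
  proteins <- list()
  cds_recs <- list()
  for (pl in placements) {
    ex <- pl$structure$exon_local
    glen <- nchar(pl$structure$tx_seq)
    if (pl$strand == "-") {
      ex <- cbind(glen - ex[, 2L], glen - ex[, 1L])
      ex <- ex[order(ex[, 1L]), , drop = FALSE]
    }
    ex_global <- cbind(pl$start + ex[, 1L], pl$start + ex[, 2L])
    gene_models[[pl$gene$id]] <- gene_model(pl$gene$id, pl$chrom, pl$strand,
                                            ex_global)
    proteins[[pl$gene$id]] <- seq_record(pl$gene$id, pl$gene$protein, "protein")
    cds_recs[[pl$gene$id]] <- seq_record(pl$gene$id, pl$gene$cds, "dna")
  }
  ann <- annotation(gene_models,
                    stats::setNames(rep(spec$chromosome_length,
                                        spec$n_chromosomes), chroms))

  iqd_all <- names(truth_domains)
  list(genome = genome,
       annotation = ann,
       proteins = proteins,
       cds = cds_recs,
       truth = list(domain_locations = truth_domains,
                    family_genes = iqd_all,
                    pair_types = truth_pairs,
                    pair_divergence = truth_div,
                    block_layout = blocks,
                    intron_truth = truth_introns))
}

#' Generate a tissue expression count table with designed preferences
#'
#' Expected counts are `baseline * fold * library_size / mean(library_size)`
#' in a gene's preferred tissue and `baseline * library_size /
#' mean(library_size)` elsewhere; negative-binomial noise is added when a
#' `dispersion` is given, otherwise counts equal their expectations.
#'
#' @param genes Character vector of gene ids.
#' @param design Data frame with columns `gene`, `tissue`, `fold` (may have
#'   zero rows: all genes at baseline).
#' @param library_sizes Named numeric vector of per-tissue read totals
#'   (> 0); names define the tissues.
#' @param seed Integer seed.
#' @param baseline Baseline expected count (default 50).
#' @param dispersion Negative-binomial size parameter; `NULL` (default)
#'   disables noise.
#' @return Integer-valued gene x tissue matrix.
#' @export
generate_expression_counts <- function(genes, design, library_sizes,
                                       seed = 1L, baseline = 50,
                                       dispersion = NULL) {
  if (any(library_sizes <= 0)) stop("zero or negative library size")
  tissues <- names(library_sizes)
  if (is.null(tissues)) stop("library_sizes must be named by tissue")
  if (nrow(design) > 0L) {
    if (!all(design$gene %in% genes)) stop("design references unknown gene(s)")
    if (!all(design$tissue %in% tissues)) stop("design references unknown tissue(s)")
    if (any(design$fold <= 0)) stop("design folds must be positive")
  }
  set.seed(seed)
  scale <- library_sizes / mean(library_sizes)
  mu <- matrix(baseline, length(genes), length(tissues),
               dimnames = list(genes, tissues))
  for (i in seq_len(nrow(design))) {
    mu[design$gene[i], design$tissue[i]] <-
      baseline * design$fold[i]
  }
  mu <- sweep(mu, 2L, scale, "*")
  if (is.null(dispersion)) {
    return(mu)
  }
  noisy <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                 size = dispersion),
                  nrow(mu), ncol(mu), dimnames = dimnames(mu))
  noisy
}

#' Generate a qPCR CT table with known fold changes
#'
#' A true fold `F` at a timepoint is encoded as a target CT shift of
#' `-log2(F)` relative to the control timepoint; the reference-gene CT is
#' constant. Gaussian noise of standard deviation `noise_sd` cycles is
#' added to the target CTs.
#'
#' @param design Data frame with columns `gene`, `timepoint`, `fold`
#'   (folds > 0). A control row (fold 1 at `control_time`) is added for any
#'   gene lacking one.
#' @param n_replicates Replicates per gene x timepoint (>= 1).
#' @param noise_sd CT noise standard deviation in cycles (default 0).
#' @param seed Integer seed.
#' @param baseline_ct Target CT at the control timepoint (default 25).
#' @param reference_ct Constant reference-gene CT (default 20).
#' @param control_time Control timepoint (default 0).
#' @return Long-format data frame with columns `gene`, `timepoint`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @export
generate_qpcr_ct <- function(design, n_replicates = 3L, noise_sd = 0,
                             seed = 1L, baseline_ct = 25, reference_ct = 20,
                             control_time = 0) {
  stopifnot(n_replicates >= 1L)
  if (any(design$fold <= 0)) stop("fold changes must be positive")
  set.seed(seed)
  rows <- list()
  for (g in unique(design$gene)) {
    sub <- design[design$gene == g, , drop = FALSE]
    if (!control_time %in% sub$timepoint) {
      sub <- rbind(sub, data.frame(gene = g, timepoint = control_time,
                                   fold = 1, stringsAsFactors = FALSE))
    }
    for (i in seq_len(nrow(sub))) {
      ct_true <- baseline_ct - log2(sub$fold[i])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, timepoint = sub$timepoint[i],
        replicate = seq_len(n_replicates),
        ct_target = ct_true + if (noise_sd > 0) {
          stats::rnorm(n_replicates, 0, noise_sd)
        } else 0,
        ct_reference = reference_ct, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
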