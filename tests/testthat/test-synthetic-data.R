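test_that("generation is deterministic for a fixed seed", {
  spec <- family_spec(n_chromosomes = 2L, chromosome_length = 1.2e5,
                      n_iqd_genes = 2L, n_background_genes = 12L,
                      tandem_pairs = 1L, segmental_blocks = 0L, seed = 5L)
  s1 <- generate_family_genome(spec)
  s2 <- generate_family_genome(spec)
  expect_identical(lapply(s1$genome, function(r) r$sequence),
                   lapply(s2$genome, function(r) r$sequence))
  expect_identical(s1$truth, s2$truth)
  expect_identical(names(s1$annotation$genes), names(s2$annotation$genes))
})

test_that("a family-free spec yields only background genes", {
  sim <- generate_family_genome(family_spec(
    n_chromosomes = 1L, chromosome_length = 2e5, n_iqd_genes = 0L,
    n_background_genes = 10L, tandem_pairs = 0L, segmental_blocks = 0L,
    seed = 2L))
  expect_length(sim$truth$domain_locations, 0L)
  expect_length(sim$annotation$genes, 10L)
  expect_true(all(grepl("^BG", names(sim$annotation$genes))))
})

test_that("requested duplicate structures appear in the truth table", {
  sim <- generate_family_genome(family_spec(
    n_chromosomes = 3L, chromosome_length = 2.5e5, n_iqd_genes = 4L,
    n_background_genes = 14L, tandem_pairs = 1L, segmental_blocks = 1L,
    seed = 3L))
  expect_equal(sum(sim$truth$pair_types$type == "tandem"), 1L)
  expect_equal(sum(sim$truth$pair_types$type == "segmental"), 1L)
  expect_length(sim$truth$block_layout, 1L)
  # every generated family entity has exactly one domain truth entry
  fam <- sim$truth$family_genes
  expect_equal(sort(names(sim$truth$domain_locations)), sort(fam))
  expect_equal(anyDuplicated(names(sim$truth$domain_locations)), 0L)
})

test_that("spec validation rejects impossible layouts", {
  expect_error(family_spec(ks_target = 0.8), "0.7")
  expect_error(family_spec(n_iqd_genes = 1L, tandem_pairs = 1L,
                           segmental_blocks = 1L), "exceed")
  expect_error(generate_family_genome(family_spec(
    n_chromosomes = 1L, chromosome_length = 8e3, n_iqd_genes = 3L,
    n_background_genes = 12L, tandem_pairs = 0L, segmental_blocks = 0L,
    seed = 1L)), "do not fit")
})

test_that("zero-divergence mutation is the identity", {
  set.seed(61)
  cds <- iqdfam:::.reverse_translate(random_protein_string(60))
  out <- mutate_codon_sequence(cds, 0, 0, seed = 1L)
  expect_equal(out$sequence, cds)
})

test_that("mutation preserves reading frame and protein length, adds no stops", {
  set.seed(62)
  for (i in 1:5) {
    prot <- random_protein_string(80)
    cds <- iqdfam:::.reverse_translate(prot)
    mut <- mutate_codon_sequence(cds, 0.05, 0.2)
    expect_equal(nchar(mut$sequence), nchar(cds))
    expect_equal(nchar(translate_cds(mut$sequence)), nchar(prot))
  }
  expect_error(mutate_codon_sequence("ATGAAA", 0, 0.71), "0.7")
})

test_that("protected codons receive no nonsynonymous changes", {
  set.seed(63)
  prot <- random_protein_string(150)
  cds <- iqdfam:::.reverse_translate(prot, add_stop = FALSE)
  mut <- mutate_codon_sequence(cds, 0.08, 0.3, protect_codons = 1:50)
  aa_in <- strsplit(prot, "")[[1L]]
  aa_out <- strsplit(translate_cds(mut$sequence, trim_stop = FALSE), "")[[1L]]
  expect_equal(aa_out[1:50], aa_in[1:50])
})

test_that("NG86 estimates of mutated pairs track the targets", {
  set.seed(64)
  est <- replicate(8, {
    cds <- iqdfam:::.reverse_translate(random_protein_string(450),
                                       add_stop = FALSE)
    mut <- mutate_codon_sequence(cds, 0.05, 0.15)
    e <- ng86_kaks(codon_alignment(cds, mut$sequence))
    c(e$ka, e$ks)
  })
  expect_equal(mean(est[1L, ]), 0.05, tolerance = 0.3)
  expect_equal(mean(est[2L, ]), 0.15, tolerance = 0.3)
})

test_that("expression counts honor the design and the noise switch", {
  libs <- c(flower = 1e6, leaf = 1e6, root = 1e6)
  design <- data.frame(gene = "g1", tissue = "flower", fold = 10)
  m <- generate_expression_counts(c("g1", "g2"), design, libs, seed = 1L)
  expect_equal(m["g1", "flower"] / m["g1", "leaf"], 10)
  expect_equal(unname(m["g2", ]), rep(50, 3), ignore_attr = TRUE)

  m2 <- generate_expression_counts(c("g1", "g2"), design, libs, seed = 1L,
                                   dispersion = 10)
  m3 <- generate_expression_counts(c("g1", "g2"), design, libs, seed = 1L,
                                   dispersion = 10)
  expect_identical(m2, m3)
  expect_equal(names(which.max(m2["g1", ])), "flower")

  empty <- data.frame(gene = character(0), tissue = character(0),
                      fold = numeric(0))
  m4 <- generate_expression_counts(c("g1"), empty, libs, seed = 1L)
  expect_true(all(m4 == 50))
  expect_error(generate_expression_counts("g1", empty, c(flower = 0)),
               "library size")
})

test_that("CT tables encode folds as -log2(F) target shifts", {
  design <- data.frame(gene = "g", timepoint = 2, fold = 2)
  ct <- generate_qpcr_ct(design, n_replicates = 2L, noise_sd = 0, seed = 1L)
  ctrl <- ct[ct$timepoint == 0, ]
  treat <- ct[ct$timepoint == 2, ]
  expect_equal(unique(treat$ct_target), unique(ctrl$ct_target) - 1)
  expect_equal(unique(ct$ct_reference), 20)
  expect_error(generate_qpcr_ct(data.frame(gene = "g", timepoint = 1,
                                           fold = -2)), "positive")
  # identical seeds give identical tables
  ct2 <- generate_qpcr_ct(design, n_replicates = 2L, noise_sd = 0.3, seed = 9L)
  ct3 <- generate_qpcr_ct(design, n_replicates = 2L, noise_sd = 0.3, seed = 9L)
  expect_identical(ct2, ct3)
})

test_that("noisy qPCR folds average back to the design within 15%", {
  design <- data.frame(gene = "g", timepoint = 4, fold = 5)
  folds <- vapply(1:20, function(sd) {
    ct <- generate_qpcr_ct(design, n_replicates = 3L, noise_sd = 0.2,
                           seed = sd)
    f <- ddct_fold_table(ct)
    f$fold[f$timepoint == 4]
  }, numeric(1L))
  expect_equal(mean(folds), 5, tolerance = 0.15)
})
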