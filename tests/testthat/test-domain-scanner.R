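test_that("motif patterns match their defining examples", {
  hit <- scan_motif(seq_record("p", "IQAAARGAAAR", "protein"), "IQ_strict")
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$start, hit$end), c(1L, 11L))

  relaxed_only <- "LQAAARAAAAK"
  expect_equal(nrow(scan_motif(relaxed_only, "IQ_strict")), 0L)
  r <- scan_motif(relaxed_only, "IQ_relaxed")
  expect_equal(nrow(r), 1L)
  expect_equal(r$matched_seq, relaxed_only)

  h1510 <- scan_motif("FAAAIAAAAW", "M_1_5_10")
  expect_equal(c(h1510$start, h1510$end), c(1L, 10L))

  h1814 <- scan_motif("FAAAAAAFAAAAAW", "M_1_8_14")
  expect_equal(c(h1814$start, h1814$end), c(1L, 14L))
})

test_that("overlapping motif hits are all reported, sorted by start", {
  # two overlapping strict IQ hits: second IQ starts before the first ends
  s <- "IQAAARGAAARIQAAARGAAAR"
  hits <- scan_motif(s, "IQ_strict")
  expect_equal(hits$start, c(1L, 12L))
  # relaxed pattern overlapping itself
  s2 <- "VQIQAARAARGKAARK"
  r <- scan_motif(s2, "IQ_relaxed")
  expect_true(all(diff(r$start) > 0L))
})

test_that("every strict IQ hit is also a relaxed hit at the same position", {
  set.seed(5)
  for (i in 1:25) {
    s <- random_protein_string(120)
    strict <- scan_motif(s, "IQ_strict")
    relaxed <- scan_motif(s, "IQ_relaxed")
    expect_true(all(strict$start %in% relaxed$start))
  }
})

test_that("scan is invariant under renaming and shifts under prefixing", {
  set.seed(6)
  s <- random_protein_string(150)
  h1 <- scan_motif(seq_record("name1", s, "protein"), "M_1_5_10")
  h2 <- scan_motif(seq_record("other", s, "protein"), "M_1_5_10")
  expect_equal(h1[, -1L], h2[, -1L])
  k <- 7L
  shifted <- scan_motif(paste0(strrep("G", k), s), "M_1_5_10")
  expect_equal(shifted$start, h1$start + k)
})

test_that("scan_motif refuses nucleotide records", {
  expect_error(scan_motif(seq_record("d", "ACGT", "dna"), "IQ_strict"),
               "protein")
})

test_that("the canonical template yields one full-spec domain call", {
  prot <- seq_record("tpl", paste0(strrep("G", 30), canonical_iq67_template(),
                                   strrep("G", 40)), "protein")
  doms <- call_iq67_domains(prot)
  expect_length(doms, 1L)
  d <- doms[[1L]]
  expect_equal(c(d$start, d$end), c(31L, 97L))
  expect_equal(nrow(d$iq_hits), 3L)
  expect_equal(nrow(d$iq_strict_hits), 3L)
  expect_true(d$spacing_ok)
  expect_gte(nrow(d$m1510_hits), 1L)
  expect_gte(nrow(d$m1814_hits), 1L)
})

test_that("domain calls are absent from poly-alanine and short proteins", {
  expect_length(call_iq67_domains(seq_record("pa", strrep("A", 200),
                                             "protein")), 0L)
  expect_warning(
    out <- call_iq67_domains(seq_record("short", strrep("A", 50), "protein")),
    "shorter than 67")
  expect_length(out, 0L)
})

test_that("overlapping candidate windows merge to the leftmost call", {
  # two templates 20 residues apart: second anchor overlaps the first window
  tpl <- canonical_iq67_template()
  prot <- seq_record("two", paste0(tpl, strrep("G", 20), tpl), "protein")
  doms <- call_iq67_domains(prot)
  expect_equal(vapply(doms, function(d) d$start, integer(1L)), c(1L, 88L))
})

test_that("implanted domains are recovered exactly on the small genome", {
  sim <- small_sim()
  hits <- scan_proteome(sim$proteins[sim$truth$family_genes])
  expect_equal(nrow(hits), length(sim$truth$family_genes))
  for (g in sim$truth$family_genes) {
    tr <- sim$truth$domain_locations[[g]]
    h <- hits[hits$protein_id == g, ]
    expect_equal(c(h$dom_start, h$dom_end), unname(tr))
    expect_true(h$spacing_ok)
    expect_equal(h$n_iq, 3L)
  }
})

test_that("molecular weight and serine fraction follow the mass table", {
  p <- protein_properties("GGGGG")
  expect_equal(p$molecular_weight * 1000, 5 * 57.0519 + 18.01524,
               tolerance = 1e-6)
  expect_equal(protein_properties("SSSS")$serine_fraction, 1)
  expect_equal(protein_properties("GGGGS")$serine_fraction, 0.2)
  expect_error(protein_properties("GGXGG"), "position 3")
})

test_that("pI equals the fine-grid root of the net-charge function", {
  seqs <- c("GGGGG", "KKKDDE", "MKVRRHSTY", random_protein_string(40))
  set.seed(8)
  for (s in seqs) {
    got <- protein_properties(s)$isoelectric_point
    counts <- table(factor(strsplit(s, "")[[1L]],
                           levels = strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1L]]))
    counts <- stats::setNames(as.integer(counts), names(counts))
    grid <- seq(0, 14, by = 1e-4)
    charge <- protein_net_charge(counts, grid)
    root <- grid[which.min(abs(charge))]
    expect_equal(got, root, tolerance = 2e-4)
  }
})

test_that("ORF-to-protein arithmetic includes the stop codon", {
  expect_equal(orf_to_protein_length(c(1263, 426)), c(420L, 141L))
  expect_error(orf_to_protein_length(100), "divisible by 3")
})
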