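test_that("homolog matching keeps best non-self partners above threshold", {
  set.seed(21)
  shared <- random_protein_string(200)
  prots_a <- list(x = seq_record("x", shared, "protein"),
                  u = seq_record("u", random_protein_string(180), "protein"))
  prots_b <- list(y = seq_record("y", shared, "protein"),
                  v = seq_record("v", random_protein_string(180), "protein"))
  m <- match_homologs(prots_a, prots_b)
  expect_equal(m$gene_a, "x")
  expect_equal(m$gene_b, "y")
  expect_true(m$reciprocal)

  # a protein matching only its own id is excluded ("non-self")
  prots_b2 <- list(x = seq_record("x", shared, "protein"))
  m2 <- match_homologs(prots_a, prots_b2)
  expect_equal(nrow(m2), 0L)

  expect_warning(match_homologs(list(), prots_b), "empty")
})

test_that("unrelated random proteins stay below the default threshold", {
  set.seed(22)
  n_hit <- 0L
  for (i in 1:30) {
    a <- list(p = seq_record("p", random_protein_string(sample(150:400, 1L)),
                             "protein"))
    b <- list(q = seq_record("q", random_protein_string(sample(150:400, 1L)),
                             "protein"))
    n_hit <- n_hit + nrow(match_homologs(a, b))
  }
  expect_equal(n_hit, 0L)
})

test_that("implanted segmental blocks are detected with enough pairs", {
  sim <- small_sim()
  ann <- sim$annotation
  for (bl in sim$truth$block_layout) {
    blk <- detect_block(ann$genes[[bl$anchor_pair[1L]]],
                        ann$genes[[bl$anchor_pair[2L]]],
                        ann, ann, sim$proteins, sim$proteins)
    expect_false(is.null(blk))
    expect_gte(nrow(blk$conserved_pairs), length(bl$genes_a))
    expect_true(all(bl$genes_a %in% blk$genes_a))
    expect_true(all(bl$genes_b %in% blk$genes_b))
    expect_true(is_large_scale_duplication(blk))
  }
})

test_that("two shared homologs are not enough for a block", {
  # two genomes sharing only the anchor and one flanking gene
  mk_ann <- function(prefix) {
    toy_annotation(list(
      list(id = paste0(prefix, "anchor"), chrom = paste0(prefix, "c"),
           start = 50000L, end = 51000L),
      list(id = paste0(prefix, "flank"), chrom = paste0(prefix, "c"),
           start = 60000L, end = 61000L)),
      chrom_len = 2e5)
  }
  set.seed(23)
  anchor_seq <- random_protein_string(250)
  flank_seq <- random_protein_string(250)
  prot <- function(prefix) {
    stats::setNames(list(
      seq_record(paste0(prefix, "anchor"), anchor_seq, "protein"),
      seq_record(paste0(prefix, "flank"), flank_seq, "protein")),
      paste0(prefix, c("anchor", "flank")))
  }
  ann_a <- mk_ann("a"); ann_b <- mk_ann("b")
  blk <- detect_block(ann_a$genes[["aanchor"]], ann_b$genes[["banchor"]],
                      ann_a, ann_b, prot("a"), prot("b"))
  expect_null(blk)
})

test_that("the 100-kb window bounds the genes entering a segment", {
  sim <- small_sim()
  ann <- sim$annotation
  bl <- sim$truth$block_layout[[1L]]
  anchor <- ann$genes[[bl$anchor_pair[1L]]]
  blk <- detect_block(anchor, ann$genes[[bl$anchor_pair[2L]]],
                      ann, ann, sim$proteins, sim$proteins)
  lo <- gene_start(anchor) - 1e5
  hi <- gene_end(anchor) + 1e5
  for (id in blk$genes_a) {
    expect_gte(gene_start(ann$genes[[id]]), lo)
    expect_lte(gene_end(ann$genes[[id]]), hi)
  }
})

test_that("synteny quality follows 2P / (Ga + Gb)", {
  expect_equal(synteny_quality(toy_block(5L, 10L, 10L)), 50)
  expect_equal(synteny_quality(toy_block(10L, 10L, 10L)), 100)
  expect_equal(synteny_quality(toy_block(1L, 10L, 10L)), 10)
  # swapping segments leaves quality unchanged
  b <- toy_block(4L, 8L, 12L)
  swapped <- b
  swapped$genes_a <- b$genes_b
  swapped$genes_b <- b$genes_a
  expect_equal(synteny_quality(b), synteny_quality(swapped))
  # an unpaired gene strictly lowers quality
  bigger <- b
  bigger$genes_a <- c(b$genes_a, "extra")
  expect_lt(synteny_quality(bigger), synteny_quality(b))
  empty <- b
  empty$genes_a <- character(0)
  expect_error(synteny_quality(empty), "empty")
})

test_that("large-scale duplication needs five flanking matched pairs", {
  expect_true(is_large_scale_duplication(toy_block(6L, 10L, 10L)))   # 5 flanking
  expect_false(is_large_scale_duplication(toy_block(5L, 10L, 10L)))  # 4 flanking
  expect_false(is_large_scale_duplication(toy_block(1L, 10L, 10L)))  # anchor only
})

test_that("implanted blocks keep their collinear (same) orientation", {
  sim <- small_sim()
  ann <- sim$annotation
  bl <- sim$truth$block_layout[[1L]]
  blk <- detect_block(ann$genes[[bl$anchor_pair[1L]]],
                      ann$genes[[bl$anchor_pair[2L]]],
                      ann, ann, sim$proteins, sim$proteins)
  expect_equal(blk$orientation, "same")
})
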