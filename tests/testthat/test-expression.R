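test_that("RPKM follows count * 1e9 / (length * library)", {
  m <- matrix(10, 1L, 1L, dimnames = list("g", "t"))
  expect_equal(rpkm_normalize(m, c(g = 1000), c(t = 1e6))[1L, 1L], 10)

  counts <- matrix(c(10, 0, 40, 25), 2L, 2L,
                   dimnames = list(c("g1", "g2"), c("t1", "t2")))
  lens <- c(g1 = 500, g2 = 2000)
  libs <- c(t1 = 1e6, t2 = 2e6)
  r1 <- rpkm_normalize(counts, lens, libs)
  # uniform count scaling with recomputed library sizes is invariant
  r2 <- rpkm_normalize(counts * 5, lens, libs * 5)
  expect_equal(r1, r2)
  expect_equal(r1["g2", "t1"], 0)
  expect_error(rpkm_normalize(matrix(-1, 1, 1, dimnames = list("g", "t")),
                              c(g = 100), c(t = 1e6)), "negative")
})

test_that("correlation distance handles perfect and anti correlation", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), g3 = c(3, 2, 1))
  d <- as.matrix(correlation_distance(m))
  expect_equal(d["g1", "g2"], 0)
  expect_equal(d["g1", "g3"], 2)
})

test_that("clustering merges identical profiles first, anticorrelated last", {
  m <- rbind(a_flat = c(5, 5, 4, 6),
             up1 = c(1, 2, 3, 4), up2 = c(2, 4, 6, 8),
             down = c(4, 3, 2, 1))
  hc <- cluster_genes(m)
  first <- sort(hc$labels[-hc$merge[1L, ]])
  expect_equal(first, c("up1", "up2"))
  # the final merge joins the anticorrelated branch
  expect_equal(max(hc$height), 2, tolerance = 1e-9)
})

test_that("clustering is invariant to input gene order", {
  set.seed(51)
  m <- matrix(rnorm(40), 8L, 5L,
              dimnames = list(paste0("g", 1:8), paste0("t", 1:5)))
  h1 <- cluster_genes(m)
  perm <- sample(1:8)
  h2 <- cluster_genes(m[perm, ])
  expect_equal(stats::cophenetic(h1), stats::cophenetic(h2))
})

test_that("constant profiles cluster at unit distance with a warning", {
  m <- rbind(flat = c(3, 3, 3), g1 = c(1, 2, 3), g2 = c(1, 2, 4))
  expect_warning(d <- correlation_distance(m), "constant")
  dm <- as.matrix(d)
  expect_equal(dm["flat", "g1"], 1)
  expect_equal(dm["flat", "g2"], 1)
})

test_that("tissue preferences use argmax with alphabetical tie-break", {
  m <- rbind(g1 = c(F = 30, R = 3, YL = 5),
             g2 = c(F = 2, R = 2, YL = 2),
             g3 = c(F = 0, R = 0, YL = 0))
  tp <- tissue_preference(m)
  expect_equal(tp$preferred, c("F", "F", "not detected"))
  expect_equal(tp$single_tissue, c(TRUE, FALSE, FALSE))
})

test_that("2^-ddCt reproduces designed folds and normalizes the control to 1", {
  expect_equal(relative_expression_ddct(20, 15, 21, 15), 2)
  expect_equal(relative_expression_ddct(21, 15, 21, 15), 1)
  expect_equal(relative_expression_ddct(22, 15, 21, 15), 0.5)
  # replicate CTs are averaged before differencing
  expect_equal(relative_expression_ddct(c(20, 22), c(15, 15), 21, 15), 1)
  expect_error(relative_expression_ddct(20, NA, 21, 15), "reference")
})

test_that("one cycle of target CT exactly doubles the fold", {
  base <- relative_expression_ddct(24, 15, 21, 15)
  expect_equal(relative_expression_ddct(23, 15, 21, 15), 2 * base)
})

test_that("fold tables recover generator designs exactly at zero noise", {
  design <- data.frame(gene = c("gA", "gA", "gB"),
                       timepoint = c(1, 4, 4),
                       fold = c(2, 26, 0.3))
  ct <- generate_qpcr_ct(design, n_replicates = 3L, noise_sd = 0, seed = 5L)
  folds <- ddct_fold_table(ct)
  expect_equal(folds$fold[folds$gene == "gA" & folds$timepoint == 0], 1)
  expect_equal(folds$fold[folds$gene == "gA" & folds$timepoint == 1], 2)
  expect_equal(folds$fold[folds$gene == "gA" & folds$timepoint == 4], 26)
  expect_equal(folds$fold[folds$gene == "gB" & folds$timepoint == 4], 0.3)
})

test_that("regulation calls follow the 0.5 / 2-fold boundaries", {
  expect_equal(regulation_call(c(0.3, 0.4, 0.2)), "down")
  expect_equal(regulation_call(c(1.1, 26.0, 3.0)), "up")
  expect_equal(regulation_call(c(0.3, 5.0)), "mixed")
  expect_equal(regulation_call(c(0.8, 1.5)), "unchanged")
  # a fold of exactly 0.5 is not "down"
  expect_equal(regulation_call(c(0.5, 0.6)), "unchanged")
})
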