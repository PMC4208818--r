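# Brute-force least-squares topology oracle for 4 taxa: enumerate the three
# unrooted quartet topologies, fit branch lengths by non-negative least
# squares on the path-length design, and return the topology with minimal
# residual sum of squares.
.quartet_oracle <- function(dm) {
  labs <- rownames(dm)
  splits <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L))
  best <- NULL
  for (s in splits) {
    pair1 <- s
    pair2 <- setdiff(1:4, s)
    # unrooted quartet (A,B|C,D): 5 branches a, b, c, d, internal e
    # path lengths: AB=a+b, CD=c+d, AC=a+e+c, AD=a+e+d, BC=b+e+c, BD=b+e+d
    idx <- function(i, j) dm[labs[i], labs[j]]
    a_ <- pair1[1L]; b_ <- pair1[2L]; c_ <- pair2[1L]; d_ <- pair2[2L]
    X <- rbind(c(1, 1, 0, 0, 0),
               c(0, 0, 1, 1, 0),
               c(1, 0, 1, 0, 1),
               c(1, 0, 0, 1, 1),
               c(0, 1, 1, 0, 1),
               c(0, 1, 0, 1, 1))
    y <- c(idx(a_, b_), idx(c_, d_), idx(a_, c_), idx(a_, d_),
           idx(b_, c_), idx(b_, d_))
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, split = sort(labs[pair1]))
    }
  }
  best$split
}

.cherry_splits <- function(tree) {
  sp <- sister_pairs(tree, min_support = 0)
  lapply(seq_len(nrow(sp)), function(i) c(sp$gene_a[i], sp$gene_b[i]))
}

test_that("p-distances count differing sites over comparable columns", {
  aln <- list(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAA")
  expect_equal(pdistance_matrix(aln)["s1", "s2"], 0)

  aln2 <- list(s1 = "AAAAAAAAAA", s2 = "CAAAAAAAAA")
  expect_equal(pdistance_matrix(aln2)["s1", "s2"], 0.1)

  aln3 <- list(s1 = "AAAA", s2 = "CCCC")
  expect_equal(pdistance_matrix(aln3)["s1", "s2"], 1)

  # gapped columns are excluded pairwise
  aln4 <- list(s1 = "A-AAA", s2 = "ACCAA")
  expect_equal(pdistance_matrix(aln4)["s1", "s2"], 0.25)

  expect_error(pdistance_matrix(list(s1 = "---A", s2 = "AAA-")),
               "no comparable")
})

test_that("NJ recovers topology and branch lengths on an additive quartet", {
  # tree ((A:1,B:1):1,(C:2,D:2)) -> additive distances
  dm <- matrix(c(0, 2, 4, 4,
                 2, 0, 4, 4,
                 4, 4, 0, 4,
                 4, 4, 4, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(dm)
  oracle_split <- .quartet_oracle(dm)
  cherries <- .cherry_splits(tr)
  expect_true(any(vapply(cherries, identical, logical(1L), oracle_split)))
  # patristic distances reproduce the additive input exactly
  patristic <- stats::cophenetic(tr)[rownames(dm), colnames(dm)]
  expect_equal(patristic, dm, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("NJ recovers the generating topology on random additive matrices", {
  set.seed(41)
  for (i in 1:20) {
    gen <- ape::rtree(6L, rooted = FALSE)
    gen$edge.length <- stats::runif(nrow(gen$edge), 0.2, 2)
    dm <- stats::cophenetic(gen)
    est <- nj_tree(dm[gen$tip.label, gen$tip.label])
    expect_equal(ape::dist.topo(ape::unroot(gen), ape::unroot(est)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ handles the three-taxon case and label permutations", {
  dm <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")

  set.seed(42)
  gen <- ape::rtree(6L, rooted = FALSE)
  dm6 <- stats::cophenetic(gen)
  perm <- sample(rownames(dm6))
  t1 <- nj_tree(dm6)
  t2 <- nj_tree(dm6[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("bootstrap gives full support to exact duplicates and is seeded", {
  set.seed(43)
  base <- random_protein_string(80)
  far1 <- random_protein_string(80)
  far2 <- random_protein_string(80)
  aln <- list(dup1 = base, dup2 = base, far1 = far1, far2 = far2)
  t1 <- bootstrap_support(aln, n_reps = 30L, seed = 7L)
  sp <- sister_pairs(t1, min_support = 0.99)
  expect_true(any(sp$gene_a == "dup1" & sp$gene_b == "dup2"))

  t2 <- bootstrap_support(aln, n_reps = 30L, seed = 7L)
  expect_identical(t1$node.label, t2$node.label)
})

test_that("sister pairs respect the support threshold", {
  tree <- ape::read.tree(text = "((A:1,B:1)0.99:1,(C:1,D:1)0.30:1);")
  tree$node.label <- as.numeric(tree$node.label)
  sp <- sister_pairs(tree, min_support = 0.5)
  expect_equal(nrow(sp), 1L)
  expect_equal(c(sp$gene_a, sp$gene_b), c("A", "B"))
  # caterpillar tree with no supported cherries
  cat_tree <- ape::read.tree(text = "(A:1,(B:1,(C:1,D:1)0.2:1)0.2:1);")
  cat_tree$node.label <- as.numeric(cat_tree$node.label)
  expect_equal(nrow(sister_pairs(cat_tree, min_support = 0.5)), 0L)
})
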