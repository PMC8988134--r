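test_that("median-of-ratios size factors match hand calculation", {
  sf <- size_factors(toy_counts())
  expect_equal(sf$size_factor, c(sqrt(0.5), sqrt(2)), tolerance = 1e-6)

  same <- tibble::tibble(g = c("a", "b"), s1 = c(5, 9), s2 = c(5, 9), s3 = c(5, 9))
  expect_equal(size_factors(same)$size_factor, rep(1, 3))

  # scaling equivariance: doubling one column doubles its factor relative
  # to the others
  doubled <- toy_counts()
  doubled$s2 <- doubled$s2 * 2
  f0 <- size_factors(toy_counts())$size_factor
  f1 <- size_factors(doubled)$size_factor
  expect_equal((f1[2] / f1[1]) / (f0[2] / f0[1]), 2, tolerance = 1e-6)
})

test_that("the shifted-log transform is exact on small counts and monotone", {
  cm <- tibble::tibble(g = c("a", "b", "c"), s1 = c(0, 3, 1), s2 = c(0, 3, 7))
  v <- vst_transform(cm, factors = rep(1, 2))
  expect_equal(v$s1, c(0, 2, 1))
  expect_equal(v$s2[3], 3)
  expect_true(v$s2[3] > v$s1[3])  # 7 > 1 preserved
})

test_that("method-of-moments dispersion recovers planted values", {
  design <- tibble::tibble(sample = c("s1", "s2", "s3"), condition = "c1")
  a <- sqrt(600)
  cm <- matrix(c(100 - a, 100, 100 + a, 50, 50, 50), nrow = 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), design$sample))
  d <- estimate_dispersion(cm, design, factors = rep(1, 3))
  expect_equal(d$dispersion[1], 0.05, tolerance = 1e-10)   # (600-100)/100^2
  expect_equal(d$dispersion[2], 1e-8)                      # constant -> floor

  set.seed(1)
  pois <- matrix(rpois(2000 * 6, 200), 2000, 6,
                 dimnames = list(paste0("g", 1:2000), paste0("s", 1:6)))
  dp <- estimate_dispersion(pois, tibble::tibble(sample = colnames(pois),
                                                 condition = rep(c("a", "b"), each = 3)),
                            factors = rep(1, 6))
  expect_lt(median(dp$dispersion), 0.005)
})

test_that("the Wald contrast recovers planted fold changes", {
  set.seed(2)
  n <- 500
  mu <- 500
  cm <- cbind(matrix(rnbinom(n * 3, mu = mu, size = 100), n),
              matrix(rnbinom(n * 3, mu = 4 * mu, size = 100), n))
  dimnames(cm) <- list(paste0("g", 1:n), paste0("s", 1:6))
  design <- tibble::tibble(sample = colnames(cm),
                           condition = rep(c("a", "b"), each = 3))
  w <- wald_contrast(cm, design, "a", "b", factors = rep(1, 6))
  expect_equal(median(w$log2FC), 2, tolerance = 0.05)
  expect_true(all(w$padj >= w$p, na.rm = TRUE))
  expect_true(all(w$p >= 0 & w$p <= 1, na.rm = TRUE))
})

test_that("degenerate features are reported NA and excluded from BH", {
  cm <- matrix(c(0, 0, 0, 0, 10, 12, 30, 35), nrow = 2, byrow = TRUE,
               dimnames = list(c("zero", "ok"), paste0("s", 1:4)))
  design <- tibble::tibble(sample = colnames(cm),
                           condition = rep(c("a", "b"), each = 2))
  w <- wald_contrast(cm, design, "a", "b", factors = rep(1, 4))
  expect_true(is.na(w$log2FC[1]) && is.na(w$padj[1]))
  expect_false(is.na(w$padj[2]))
})

test_that("the LRT detects planted condition effects and agrees with Wald", {
  set.seed(3)
  n <- 300
  base <- rlnorm(n, log(300), 0.5)
  cm <- cbind(matrix(rnbinom(n * 3, mu = base, size = 100), n),
              matrix(rnbinom(n * 3, mu = 8 * base, size = 100), n),
              matrix(rnbinom(n * 3, mu = 3 * base, size = 100), n))
  dimnames(cm) <- list(paste0("g", 1:n), paste0("s", 1:9))
  design <- tibble::tibble(sample = colnames(cm),
                           condition = rep(c("u", "l", "j"), each = 3))
  # planted per-condition effects are shared by all features, so depth
  # factors are fixed at 1 rather than estimated from composition;
  # the asymptotic chi-squared reference resolves extreme tail p-values,
  # the default F reference saturates at its denominator df but still
  # flags every affected feature decisively
  lc <- lrt_test(cm, design, conditions = c("u", "l", "j"),
                 factors = rep(1, 9), stat_dist = "chisq")
  expect_gt(mean(lc$padj < 1e-6), 0.99)
  expect_equal(unique(lc$df), 2)
  l <- lrt_test(cm, design, conditions = c("u", "l", "j"), factors = rep(1, 9))
  expect_gt(mean(l$padj < 1e-3), 0.99)

  # two-condition designs: Wald and LRT rank features near-identically
  sub <- design$condition != "j"
  w2 <- wald_contrast(cm[, sub], design[sub, ], "u", "l")
  l2 <- lrt_test(cm[, sub], design[sub, ], conditions = c("u", "l"))
  rho <- cor(-log10(w2$p), -log10(l2$p), method = "spearman")
  expect_gt(rho, 0.95)
  expect_error(lrt_test(cm, design, conditions = "u"), ">=2")
})

test_that("normalization recovers planted depth factors", {
  sim <- null_sim()
  sf <- size_factors(sim$rna$counts)
  planted <- sim$rna$size_factors$size_factor
  expect_gt(cor(sf$size_factor, planted), 0.99)
})

test_that("the NB engine agrees with an established reference implementation", {
  skip_if_not_installed("DESeq2")
  sim <- memo("sim_small_de", simulate_dataset(sim_config(n_genes = 300, seed = 71)))
  m <- as_count_matrix(sim$rna$counts)
  storage.mode(m) <- "integer"
  design <- as.data.frame(sim$rna$design)
  rownames(design) <- design$sample
  design$condition <- factor(design$condition, levels = c("unstim", "LPS", "LPS_JQ1"))
  dds <- DESeq2::DESeqDataSetFromMatrix(m, design, ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds, contrast = c("condition", "LPS", "unstim"))
  w <- wald_contrast(sim$rna$counts, sim$rna$design, "unstim", "LPS")
  ok <- complete.cases(res$log2FoldChange, w$log2FC)
  expect_gt(cor(res$log2FoldChange[ok], w$log2FC[ok]), 0.98)
  expect_gt(cor(-log10(res$pvalue[ok] + 1e-300), -log10(w$p[ok] + 1e-300),
                method = "spearman"), 0.9)
  expect_gt(cor(DESeq2::sizeFactors(dds),
                size_factors(sim$rna$counts)$size_factor), 0.999)
})

test_that("BH adjustment matches hand calculations and stays monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.01, NA, 0.03)), c(0.02, NA, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  p <- sort(runif(100))
  expect_true(all(diff(bh_adjust(p)) >= -1e-12))
})

test_that("PCA selects top-variance features and matches a covariance oracle", {
  set.seed(5)
  # rank-1 structure
  u <- rnorm(50)
  v <- rnorm(6)
  m1 <- u %o% v
  rownames(m1) <- paste0("g", 1:50); colnames(m1) <- paste0("s", 1:6)
  p1 <- pca_top_features(m1, k = 50)
  expect_gt(p1$var_explained[1], 0.999)

  m2 <- matrix(rnorm(200 * 6), 200, 6,
               dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  m2[1:10, ] <- m2[1:10, ] * 20
  p2 <- pca_top_features(m2, k = 10)
  expect_setequal(p2$features, paste0("g", 1:10))

  # sample scores from SVD match eigendecomposition of the sample covariance
  xc <- m2[p2$features, ] - rowMeans(m2[p2$features, ])
  ev <- eigen(crossprod(xc))
  sc <- as.matrix(p2$scores[, -1])
  for (j in 1:3) {
    expect_equal(abs(sc[, j]), abs(ev$vectors[, j] * sqrt(ev$values[j])),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})
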