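test_that("low-expression filter applies the >=4-in->=2-samples rule", {
  m <- toy_counts(c(4, 4, 0,
                    3, 5, 0,
                    4, 3, 10), 3, 3)
  kept <- filter_low_expression(m)
  expect_identical(rownames(kept), c("f01", "f03"))
  expect_identical(filter_low_expression(kept), kept)  # idempotent

  zeros <- toy_counts(rep(0, 12), 4, 3)
  expect_equal(nrow(filter_low_expression(zeros)), 0)

  set.seed(42)
  big <- matrix(rpois(500 * 6, 3), 500, 6,
                dimnames = list(sprintf("g%03d", 1:500), sprintf("s%d", 1:6)))
  kept2 <- filter_low_expression(big)
  oracle <- vapply(seq_len(nrow(big)), function(i)
    sum(big[i, ] >= 4) >= 2, logical(1))  # brute-force re-scan
  expect_identical(rownames(kept2), rownames(big)[oracle])
})

test_that("upper-quartile factors are symmetric, scale-invariant and exact", {
  m <- toy_counts(rep(c(10, 0, 7, 3, 25), each = 2), 5, 2)
  expect_equal(upper_quartile_factors(m)$factor, c(1, 1))

  m2 <- cbind(s1 = c(10, 0, 7, 3, 25), s2 = 3 * c(10, 0, 7, 3, 25))
  rownames(m2) <- sprintf("f%d", 1:5)
  expect_equal(upper_quartile_factors(m2)$factor, c(1, 1), tolerance = 1e-12)

  # direct recomputation with the stated quantile definition
  set.seed(1)
  m3 <- matrix(rpois(40, 20), 20, 2, dimnames = list(sprintf("f%d", 1:20), c("a", "b")))
  got <- upper_quartile_factors(m3)
  n <- colSums(m3)
  nz <- rowSums(m3 > 0) >= 1
  raw <- c(quantile(m3[nz, 1] / n[1], 0.75, type = 7),
           quantile(m3[nz, 2] / n[2], 0.75, type = 7))
  expect_equal(got$factor, unname(raw / exp(mean(log(raw)))), tolerance = 1e-12)

  m4 <- m3; m4[, 2] <- 0
  expect_error(upper_quartile_factors(m4), "no nonzero counts")
})

test_that("TMM factors handle proportional libraries and match a direct recomputation", {
  # 5-feature toys trigger the documented fall-back to the untrimmed mean
  m <- toy_counts(rep(c(10, 2, 7, 30, 25), each = 2), 5, 2)
  expect_warning(f_id <- tmm_factors(m)$factor, "untrimmed mean")
  expect_equal(f_id, c(1, 1))
  m2 <- cbind(s1 = c(10, 2, 7, 30, 25), s2 = 2 * c(10, 2, 7, 30, 25))
  rownames(m2) <- sprintf("f%d", 1:5)
  expect_warning(f_prop <- tmm_factors(m2)$factor, "untrimmed mean")
  expect_equal(f_prop, c(1, 1), tolerance = 1e-12)

  # 5% of features 8-fold up in sample 2: recompute the trimmed weighted mean
  set.seed(8)
  base <- rpois(400, 50) + 1
  up <- seq_len(20)
  obs <- base; obs[up] <- obs[up] * 8
  m3 <- cbind(ref = base, shift = obs)
  rownames(m3) <- sprintf("f%d", 1:400)
  got <- tmm_factors(m3, reference = "ref")
  n <- colSums(m3)
  mm <- log2((m3[, 2] / n[2]) / (m3[, 1] / n[1]))
  aa <- 0.5 * log2((m3[, 2] / n[2]) * (m3[, 1] / n[1]))
  w <- 1 / (1 / m3[, 2] - 1 / n[2] + 1 / m3[, 1] - 1 / n[1])
  nf <- length(mm)
  lo_m <- floor(nf * 0.3) + 1; hi_m <- nf + 1 - lo_m
  lo_a <- floor(nf * 0.05) + 1; hi_a <- nf + 1 - lo_a
  keep <- rank(mm) >= lo_m & rank(mm) <= hi_m & rank(aa) >= lo_a & rank(aa) <= hi_a
  raw <- c(1, 2^(sum(w[keep] * mm[keep]) / sum(w[keep])))
  expect_equal(got$factor, unname(raw / exp(mean(log(raw)))), tolerance = 1e-12)
})

test_that("TMM matches the established reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(33)
  m <- matrix(rnbinom(1000 * 4, mu = exp(rnorm(1000, 4, 1)), size = 10), 1000, 4,
              dimnames = list(sprintf("g%d", 1:1000), sprintf("s%d", 1:4)))
  m[seq_len(80), 2] <- m[seq_len(80), 2] * 6
  expect_equal(tmm_factors(m)$factor,
               unname(edgeR::calcNormFactors(m, method = "TMM")),
               tolerance = 1e-10)
})

test_that("normalization factors are invariant to column rescaling", {
  set.seed(12)
  m <- matrix(rpois(600, 30), 100, 6,
              dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:6)))
  f_uq <- upper_quartile_factors(m)$factor
  f_tmm <- tmm_factors(m)$factor
  m2 <- m; m2[, 3] <- m2[, 3] * 5
  # upper-quartile depends on counts only through count/N: exactly invariant
  expect_equal(upper_quartile_factors(m2)$factor, f_uq, tolerance = 1e-9)
  # TMM M/A values and trimming are exactly invariant, but the precision
  # weights involve absolute counts, so single-column invariance is only
  # approximate; a global rescale is exact
  expect_equal(tmm_factors(m2)$factor, f_tmm, tolerance = 0.01)
  expect_equal(tmm_factors(m * 5)$factor, f_tmm, tolerance = 1e-9)
})

test_that("normalized abundances follow the CPM formula", {
  m <- toy_counts(c(100, 200, 300, 400), 2, 2)
  fac <- structure(data.frame(sample = c("s1", "s2"),
                              lib_size = c(1e6, 1e6), factor = c(1, 1)),
                   class = c("norm_factors", "data.frame"))
  expect_equal(normalize_counts(m, fac), m + 0)
  fac2 <- fac; fac2$lib_size[2] <- 2e6
  out <- normalize_counts(m, fac2)
  expect_equal(out[, 2], m[, 2] / 2)
  expect_equal(out["f01", "s1"], 100 / (1e6 * 1) * 1e6)  # hand formula
  expect_equal(normalize_counts(m, fac, log = TRUE), log2(m + 0.5))
})

test_that("Spearman matrix behaves on known rank structures", {
  x <- cbind(a = c(1, 5, 3, 9), b = c(2, 10, 6, 18), c = c(9, 1, 5, 0.5))
  rho <- sample_spearman_matrix(x)
  expect_equal(rho["a", "b"], 1)    # identical ranks
  expect_equal(rho["a", "c"], -1)   # reversed ranks
  expect_equal(diag(rho), c(a = 1, b = 1, c = 1))
  expect_equal(rho, t(rho))

  set.seed(4)
  y <- matrix(rnorm(25), 5, 5, dimnames = list(NULL, letters[1:5]))
  rho2 <- sample_spearman_matrix(y)
  hand <- cor(rank(y[, 1]), rank(y[, 2]))  # rank-and-correlate oracle
  expect_equal(rho2["a", "b"], hand)
})

test_that("PCA embedding matches an independent eigendecomposition", {
  v <- c(1, 2, 3, 4, 5)
  rank1 <- outer(v, c(1, 2, 4, 8))
  rownames(rank1) <- sprintf("f%d", 1:5); colnames(rank1) <- sprintf("s%d", 1:4)
  p <- pca_embed(rank1, 2)
  expect_equal(p$explained_variance[1], 1)

  set.seed(5)
  x <- matrix(rnorm(60), 10, 6, dimnames = list(sprintf("f%d", 1:10),
                                                sprintf("s%d", 1:6)))
  x[, 6] <- x[, 5]                       # duplicate samples
  p2 <- pca_embed(x, 3)
  expect_equal(p2$scores["s5", ], p2$scores["s6", ])

  ev <- eigen(cov(t(x)))                 # covariance eigensolve oracle
  total <- sum(diag(cov(t(x))))
  expect_equal(p2$explained_variance, ev$values[1:3] / total, tolerance = 1e-8)
  centered <- scale(t(x), center = TRUE, scale = FALSE)
  for (j in 1:2)
    expect_equal(abs(unname(p2$scores[, j])),
                 abs(as.vector(centered %*% ev$vectors[, j])), tolerance = 1e-8)
})
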