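test_that("moments match hand arithmetic and flag degenerate input", {
  m <- feature_moments(c(1, 2, 3, 4, 5))
  expect_equal(m$mean, 3)
  expect_equal(m$variance, 2.5)
  expect_false(m$flagged)
  cst <- feature_moments(rep(4, 10))
  expect_equal(cst$variance, 0)
  expect_true(cst$flagged)
  expect_true(is.na(cst$skewness))
})

test_that("moments agree with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(1)
  x <- rexp(500)
  m <- feature_moments(x)
  expect_equal(m$skewness, e1071::skewness(x, type = 1), tolerance = 1e-10)
  expect_equal(m$kurtosis, e1071::kurtosis(x, type = 1), tolerance = 1e-10)
})

test_that("a large normal sample has near-zero shape moments", {
  set.seed(2)
  m <- feature_moments(rnorm(1e5))
  expect_lt(abs(m$skewness), 0.05)
  expect_lt(abs(m$kurtosis), 0.05)
})

test_that("pairwise correlation hits its exact special cases", {
  dup <- matrix(rep(c(1, 3, 2, 5), 3), 3, 4, byrow = TRUE)
  expect_equal(pairwise_pcc(dup), 1)
  anti <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(pairwise_pcc(anti), -1)
  set.seed(3)
  rnd <- matrix(rnorm(60 * 50), 60, 50)
  expect_lt(abs(pairwise_pcc(rnd)), 3 / sqrt(choose(60, 2)) + 0.03)
  degen <- rbind(c(1, 1, 1), c(1, 2, 3), c(2, 1, 0))
  expect_warning(p <- pairwise_pcc(degen), "zero-variance")
  expect_equal(p, -1)
})

test_that("sample entropy matches the brute-force template oracle", {
  set.seed(4)
  for (rep in 1:3) {
    x <- rnorm(30)
    got <- suppressWarnings(sample_entropy(x, m = 2, r = 0.3))
    expect_equal(got, naive_sampen(x, m = 2, r = 0.3), tolerance = 1e-12)
  }
  # a short noisy vector with no length-3 template matches is flagged
  set.seed(7)
  x <- rnorm(12)
  expect_warning(se <- sample_entropy(x, m = 2, r = 0.05),
                 "undefined")
  expect_identical(se, Inf)
})

test_that("sample entropy is zero for fully predictable sequences", {
  expect_equal(sample_entropy(rep(1, 20) + 0, m = 2, r = 0.2), 0)
  expect_equal(sample_entropy(rep(c(1, -1), 15), m = 2, r = 0.2), 0)
})

test_that("sample entropy is non-increasing in the tolerance r", {
  set.seed(5)
  x <- rnorm(80)
  r_grid <- c(0.1, 0.2, 0.35, 0.5, 1)
  se <- vapply(r_grid,
               function(r) suppressWarnings(sample_entropy(x, 2, r)),
               numeric(1))
  expect_true(all(diff(se[is.finite(se)]) <= 1e-12))
})

test_that("canonical correlation hits identity and permutation cases", {
  set.seed(6)
  a <- matrix(rnorm(40 * 6), 40, 6)
  expect_equal(cca_first(a, a), 1, tolerance = 1e-6)
  expect_equal(cca_first(a, a[, sample(6)]), 1, tolerance = 1e-6)
  b <- matrix(rnorm(40 * 6), 40, 6)
  obs <- cca_first(a, b)
  # permutation-null oracle: independent sets give CCA near the null bias
  null_dist <- vapply(1:40, function(i) {
    cca_first(a, b[sample(nrow(b)), ])
  }, numeric(1))
  expect_lt(obs, max(null_dist) + 0.15)
  expect_gt(obs, min(null_dist) - 0.15)
})

test_that("the descriptor panel has the right shape and invariances", {
  coh <- tiny_cohort(n_cvd = 2, n_normal = 2, duration = 8, seed = 7)
  fms <- lapply(lapply(coh, segment_record), ht_reduce)
  s1 <- stats_summary(fms, seed = 1)
  expect_equal(s1$statistic,
               c("mean", "variance", "skewness", "kurtosis", "pcc",
                 "sample_entropy"))
  expect_true(all(is.finite(s1$CVD)))
  expect_true(all(is.finite(s1$NORMAL)))
  cca <- attr(s1, "cca")
  expect_gte(cca, 0)
  expect_lte(cca, 1)
  # invariant to subject (hence segment-block) ordering
  s2 <- stats_summary(rev(fms), seed = 1)
  expect_equal(s2$CVD, s1$CVD, tolerance = 1e-10)
  expect_equal(s2$NORMAL, s1$NORMAL, tolerance = 1e-10)
})
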