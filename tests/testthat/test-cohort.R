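test_that("cohort dimensions and determinism follow the study design", {
  spec <- cohort_spec(n_cvd = 1, n_normal = 2, fs = 200, duration = 20,
                      seed = 7)
  coh <- generate_cohort(spec)
  expect_length(coh, 3)
  expect_true(all(vapply(coh, function(r) length(r$signal), numeric(1)) ==
                    4000))
  expect_identical(vapply(coh, `[[`, character(1), "label"),
                   c("CVD", "NORMAL", "NORMAL"))
  expect_true(all(vapply(coh, function(r) all(is.finite(r$signal)),
                         logical(1))))
  # identical (spec, seed) gives a bit-identical cohort
  expect_identical(coh, generate_cohort(spec))
  # different seed changes the signals
  spec2 <- cohort_spec(n_cvd = 1, n_normal = 2, fs = 200, duration = 20,
                       seed = 8)
  expect_false(identical(generate_cohort(spec2)[[1]]$signal,
                         coh[[1]]$signal))
})

test_that("non-integer sample counts are rejected with a sizing error", {
  expect_error(cohort_spec(fs = 200.5, duration = 10.003),
               "integer number of samples")
  expect_error(cohort_spec(morphology_shift = 1.2), "morphology_shift")
})

test_that("beat count tracks the mean heart rate at zero noise", {
  coh <- tiny_cohort(n_cvd = 2, n_normal = 2, duration = 60, noise_sd = 0,
                     artifact_rate = 0, seed = 3)
  count_peaks <- function(s) {
    i <- 2:(length(s) - 1)
    sum(s[i] > s[i - 1] & s[i] >= s[i + 1] & s[i] > 0.5 * max(s))
  }
  expected <- 72 * 60 / 60
  for (rec in coh) {
    expect_lt(abs(count_peaks(rec$signal) - expected), 0.05 * expected + 1)
  }
})

test_that("zero morphology shift makes the classes indistinguishable", {
  spec <- cohort_spec(n_cvd = 3, n_normal = 3, duration = 30,
                      morphology_shift = 0, noise_sd = 0,
                      artifact_rate = 0, seed = 5)
  coh <- generate_cohort(spec)
  m <- vapply(coh, function(r) mean(r$signal), numeric(1))
  v <- vapply(coh, function(r) var(r$signal), numeric(1))
  lab <- vapply(coh, `[[`, character(1), "label")
  # class-conditional means of beat-aligned statistics agree
  expect_lt(abs(mean(m[lab == "CVD"]) - mean(m[lab == "NORMAL"])), 5e-3)
  expect_lt(abs(mean(v[lab == "CVD"]) - mean(v[lab == "NORMAL"])), 5e-3)
})

test_that("nearest-centroid separability is monotone in morphology shift", {
  acc_at <- function(shift) {
    coh <- tiny_cohort(n_cvd = 4, n_normal = 4, duration = 40,
                       morphology_shift = shift, seed = 9)
    p <- pool_segments(lapply(coh, segment_record))
    ppgcvd:::centroid_holdout_accuracy(p$x, p$y, seq_len(ncol(p$x)))
  }
  acc <- vapply(c(0.1, 0.5, 0.9), acc_at, numeric(1))
  # non-decreasing within sampling tolerance
  expect_true(all(diff(acc) > -0.05))
  expect_gt(acc[3], acc[1] + 0.1)
})

test_that("feature blobs have the contracted geometry and determinism", {
  b <- generate_feature_blobs(50, 20, 7, seed = 4)
  expect_equal(dim(b$x), c(100, 20))
  expect_equal(sum(b$y == "CVD"), 50)
  gap <- sqrt(sum((colMeans(b$x[b$y == "CVD", ]) -
                     colMeans(b$x[b$y == "NORMAL", ]))^2))
  expect_lt(abs(gap - 7), 1.5)          # sampling noise around separation
  expect_identical(b, generate_feature_blobs(50, 20, 7, seed = 4))
  # separation 0: any classifier is label-blind (chance accuracy)
  b0 <- generate_feature_blobs(150, 10, 0, seed = 6)
  acc <- centroid_accuracy(b0$x[1:150, ], b0$y[1:150],
                           b0$x[151:300, ], b0$y[151:300])
  expect_lt(abs(acc - 0.5), 0.12)
})

test_that("strongly separated blobs are solved by the centroid oracle", {
  b <- generate_feature_blobs(200, 10, 10, seed = 2)
  acc <- centroid_accuracy(b$x[1:200, ], b$y[1:200],
                           b$x[201:400, ], b$y[201:400])
  expect_gte(acc, 0.95)
})
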