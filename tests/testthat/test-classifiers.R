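test_that("target coding maps labels and enforces the gap constraint", {
  expect_equal(code_targets(c("CVD", "NORMAL")), c(0.85, 0.1))
  expect_equal(code_targets(rep("CVD", 3)), rep(0.85, 3))
  expect_error(target_coding(0.9, 0.5), ">= 0.5")
  expect_error(code_targets(c("CVD", "other")), "labels")
})

test_that("training MSE matches closed forms and a summation oracle", {
  expect_equal(training_mse(c(0.85, 0.1), c(0.85, 0.1)), 0)
  expect_equal(training_mse(rep(0.6, 10), rep(0.5, 10)), 0.01)
  set.seed(1)
  a <- rnorm(5)
  b <- rnorm(5)
  expect_equal(training_mse(a, b), sum((a - b)^2) / 5)
  expect_error(training_mse(numeric(0), numeric(0)), "empty")
  expect_error(training_mse(1:3, 1:2), "mismatch")
})

test_that("the DFA exponent separates white noise from Brownian paths", {
  set.seed(2)
  w <- replicate(40, dfa_exponent(rnorm(2000)))
  expect_lt(abs(mean(w) - 0.5), 0.1)
  b <- replicate(40, dfa_exponent(cumsum(rnorm(2000))))
  expect_lt(abs(mean(b) - 1.5), 0.15)
})

test_that("a linear cumulative profile makes the DFA exponent undefined", {
  # a constant series has a linear (identically zero) mean-removed
  # profile, so every windowed fluctuation vanishes
  expect_warning(a <- dfa_exponent(rep(3, 200)), "vanishes")
  expect_true(is.na(a))
  # a ramp input, by contrast, has a quadratic profile and a smooth,
  # large exponent
  a2 <- dfa_exponent(seq(0, 1, length.out = 500))
  expect_gt(a2, 1.5)
})

test_that("firefly attractiveness at zero distance equals its brightness", {
  expect_equal(ppgcvd:::firefly_attractiveness(0), 0.65)
  expect_equal(ppgcvd:::firefly_attractiveness(0, alpha0 = 0.3, beta = 2),
               0.3)
  expect_lt(ppgcvd:::firefly_attractiveness(2), 0.65 * exp(-3.9))
})

test_that("SDC at zero distance scores the matching class at its maximum", {
  x_tr <- rbind(c(1, 2), c(-1, -2))
  y_tr <- c("CVD", "NORMAL")
  m <- ppg_classifier(x_tr, y_tr, "SDC")
  q_c <- ppgcvd:::sdc_class_score(m$fit$refs_c, rbind(c(1, 2)), 0.5)
  q_n <- ppgcvd:::sdc_class_score(m$fit$refs_n, rbind(c(1, 2)), 0.5)
  expect_equal(q_c, 0)                     # log exp(-lambda * 0)
  expect_lt(q_n, 0)
  expect_identical(predict(m, rbind(c(1, 2))), "CVD")
})

test_that("the BLDC boundary is the perpendicular bisector for symmetric classes", {
  set.seed(3)
  b <- generate_feature_blobs(300, 8, 6, seed = 3)
  m <- ppg_classifier(b$x, b$y, "BLDC")
  mu_c <- colMeans(b$x[b$y == "CVD", ])
  mu_n <- colMeans(b$x[b$y == "NORMAL", ])
  midpoint <- matrix((mu_c + mu_n) / 2, 1)
  sc <- predict(m, midpoint, type = "score")
  expect_lt(abs(sc - 0.5), 0.05)           # boundary point scores ~0.5
})

test_that("every classifier kind fits, predicts and thresholds consistently", {
  b <- generate_feature_blobs(150, 30, 8, seed = 4)
  tr <- 1:150
  te <- 151:300
  for (k in classifier_kinds()) {
    m <- ppg_classifier(b$x[tr, ], b$y[tr], k, seed = 7)
    expect_s3_class(m, "ppg_classifier")
    sc <- predict(m, b$x[te, ], type = "score")
    lab <- predict(m, b$x[te, ], type = "label")
    expect_true(all(is.finite(sc)))
    expect_true(all(sc >= 0 & sc <= 1))
    # thresholding scores reproduces emitted labels exactly
    expect_identical(lab, ifelse(sc >= m$threshold, "CVD", "NORMAL"))
    expect_true(all(is.finite(m$train_mse)))
    # determinism given seed
    m2 <- ppg_classifier(b$x[tr, ], b$y[tr], k, seed = 7)
    expect_identical(predict(m2, b$x[te, ], type = "score"), sc)
  }
  expect_error(ppg_classifier(b$x[tr, ], rep("CVD", 150), "PCA"),
               "both classes")
})

test_that("EM and GMM likelihood traces are monotone and traced", {
  b <- generate_feature_blobs(120, 10, 4, seed = 5)
  em <- ppg_classifier(b$x, b$y, "EM", seed = 2)
  expect_true(all(diff(em$fit$loglik) >= -1e-4 * abs(em$fit$loglik[1])))
  gmm <- ppg_classifier(b$x, b$y, "GMM", seed = 2)
  expect_true(all(diff(gmm$fit$loglik$cvd) >= -1))
  expect_true(all(diff(gmm$fit$loglik$normal) >= -1))
})

test_that("firefly and harmony best-MSE traces never increase", {
  b <- generate_feature_blobs(80, 10, 2, seed = 6)   # overlap keeps MSE > 0
  ff <- ppg_classifier(b$x, b$y, "FIREFLY", seed = 3,
                       stop = stop_rule(max_iter = 40))
  expect_true(all(diff(ff$train_mse) <= 1e-12))
  hs <- ppg_classifier(b$x, b$y, "HARMONY", seed = 3,
                       stop = stop_rule(max_iter = 200))
  expect_true(all(diff(hs$train_mse) <= 1e-12))
})

test_that("logistic regression respects the probability threshold of one half", {
  b <- generate_feature_blobs(100, 6, 8, seed = 7)
  m <- ppg_classifier(b$x, b$y, "LOGREG")
  expect_equal(m$threshold, 0.5)
  sc <- predict(m, b$x, type = "score")
  expect_identical(predict(m, b$x),
                   ifelse(sc >= 0.5, "CVD", "NORMAL"))
  # cross-check the separating direction against glm
  fit_glm <- suppressWarnings(
    stats::glm.fit(cbind(1, b$x), as.numeric(b$y == "CVD"),
                   family = stats::binomial()))
  agree <- mean((fit_glm$fitted.values >= 0.5) == (sc >= 0.5))
  expect_gte(agree, 0.98)
})

test_that("BLDC agrees with reference linear discriminant analysis", {
  skip_if_not_installed("MASS")
  b <- generate_feature_blobs(150, 8, 3, seed = 8)
  m <- ppg_classifier(b$x, b$y, "BLDC", params = list(shrinkage = 0))
  ld <- MASS::lda(b$x, grouping = b$y, prior = c(0.5, 0.5))
  ref <- as.character(predict(ld, b$x)$class)
  expect_gte(mean(predict(m, b$x) == ref), 0.99)
})

test_that("PCA classifier uses the stated 0.72 threshold and orientation", {
  b <- generate_feature_blobs(200, 10, 10, seed = 9)
  m <- ppg_classifier(b$x, b$y, "PCA")
  expect_equal(m$threshold, 0.72)
  sc <- predict(m, b$x, type = "score")
  expect_gt(mean(sc[b$y == "CVD"]), mean(sc[b$y == "NORMAL"]))
  expect_true(all(sc >= 0 & sc <= 1))
})
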