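test_that("confusion counts follow the CVD-positive convention", {
  truth <- c(rep("CVD", 10), rep("NORMAL", 10))
  cc <- confusion_counts(truth, truth)
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 10, tn = 10, fp = 0, fn = 0))
  inverted <- ifelse(truth == "CVD", "NORMAL", "CVD")
  ci <- confusion_counts(truth, inverted)
  expect_equal(unlist(ci[c("tp", "tn", "fp", "fn")]),
               c(tp = 0, tn = 0, fp = 10, fn = 10))
  # fixed 8-element pair against an exhaustive hand count
  tr8 <- c("CVD", "CVD", "NORMAL", "CVD", "NORMAL", "NORMAL", "CVD",
           "NORMAL")
  pr8 <- c("CVD", "NORMAL", "NORMAL", "CVD", "CVD", "NORMAL", "NORMAL",
           "CVD")
  c8 <- confusion_counts(tr8, pr8)
  expect_equal(unlist(c8[c("tp", "tn", "fp", "fn")]),
               c(tp = 2, tn = 2, fp = 2, fn = 2))
  expect_error(confusion_counts(tr8, pr8[1:7]), "mismatch")
})

test_that("perfect detection yields the boundary metric values", {
  m <- classification_metrics(list(tp = 100, tn = 100, fp = 0, fn = 0))
  expect_equal(m$pi, 100)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$accuracy, 100)
  expect_equal(m$gdr, 100)
  expect_equal(m$error_rate, 0)
})

test_that("metrics reproduce the printed confusion rows exactly", {
  # harmonic-search row of the published Hilbert-transform confusion table
  m <- classification_metrics(list(tp = 14400, tn = 14400, fp = 720,
                                   fn = 0))
  expect_equal(m$accuracy, 100 * 28800 / 29520, tolerance = 1e-12)
  expect_equal(m$accuracy, 97.5609756097561, tolerance = 1e-10)
  expect_equal(m$pi, 97.5, tolerance = 1e-12)
  expect_equal(m$gdr, 97.5, tolerance = 1e-12)
  expect_equal(m$sensitivity, 100, tolerance = 1e-12)
  expect_equal(m$specificity, 100 * 14400 / 15120, tolerance = 1e-12)
  expect_equal(m$specificity, 95.2380952380952, tolerance = 1e-10)
  expect_equal(m$error_rate, 100 - m$accuracy, tolerance = 0)

  # GMM row of the same table
  g <- classification_metrics(list(tp = 12960, tn = 10800, fp = 4320,
                                   fn = 1440))
  expect_equal(g$sensitivity, 90, tolerance = 1e-12)
  expect_equal(g$specificity, 100 * 10800 / 15120, tolerance = 1e-12)
  expect_equal(g$specificity, 71.4285714285714, tolerance = 1e-10)
  expect_equal(g$accuracy, 80.4878048780488, tolerance = 1e-10)
  expect_equal(g$pi, 100 * 18000 / 23760, tolerance = 1e-12)
  expect_equal(g$gdr, 100 * 19440 / 25200, tolerance = 1e-12)
})

test_that("undefined denominators are flagged as NA", {
  expect_warning(m <- classification_metrics(list(tp = 0, tn = 5, fp = 3,
                                                  fn = 0)),
                 "sensitivity")
  expect_true(is.na(m$sensitivity))
  expect_false(is.na(m$accuracy))
})

test_that("fold assignment is a stratified partition", {
  y <- rep(c("CVD", "NORMAL"), c(55, 45))
  f <- make_folds(y, n_folds = 10, seed = 1)
  expect_true(all(table(f) %in% 9:11))
  for (k in 1:10) {
    expect_true(all(c("CVD", "NORMAL") %in% y[f == k]))
  }
  # subject-level folds keep subjects intact
  subj <- rep(sprintf("S%02d", 1:20), each = 5)
  ys <- rep(rep(c("CVD", "NORMAL"), each = 10), each = 5)
  fs <- make_folds(ys, subj, n_folds = 5, subject_level = TRUE, seed = 2)
  expect_true(all(tapply(fs, subj, function(v) length(unique(v))) == 1))
})

test_that("the evaluation grid bookkeeping adds up", {
  coh <- tiny_cohort(n_cvd = 2, n_normal = 2, duration = 15,
                     morphology_shift = 0.9, seed = 12)
  segs <- lapply(coh, segment_record)
  grid <- run_grid(segs, methods = c("HT"), kinds = c("BLDC", "SDC"),
                   n_folds = 5, seed = 3)
  expect_s3_class(grid, "ppg_grid")
  # 1 method x 2 classifiers x 5 folds fold records, 2 averaged rows
  expect_equal(nrow(grid$folds), 10)
  expect_equal(nrow(grid$summary), 2)
  # per-fold evaluated segments sum to the cohort total per cell
  per_cell <- tapply(grid$folds$n_test,
                     paste(grid$folds$method, grid$folds$classifier), sum)
  expect_true(all(per_cell == 60))
  counts <- grid$folds$tp + grid$folds$tn + grid$folds$fp + grid$folds$fn
  expect_equal(counts, grid$folds$n_test)
  # accuracy + error = 100 exactly on every fold and averaged cell
  expect_true(all(grid$folds$accuracy + grid$folds$error_rate == 100))
  expect_true(all(abs(grid$summary$accuracy + grid$summary$error_rate -
                        100) < 1e-12))
})

test_that("a strongly separated cohort is learned by margin-based kinds", {
  coh <- tiny_cohort(n_cvd = 3, n_normal = 3, duration = 25,
                     morphology_shift = 0.9, seed = 13)
  segs <- lapply(coh, segment_record)
  grid <- run_grid(segs, methods = "HT",
                   kinds = c("LOGREG", "BLDC", "SDC", "KNN_PAC"),
                   n_folds = 5, seed = 4)
  expect_true(all(grid$summary$accuracy >= 90))
})

test_that("grids are reproducible under a fixed seed", {
  coh <- tiny_cohort(n_cvd = 2, n_normal = 2, duration = 10, seed = 14)
  segs <- lapply(coh, segment_record)
  g1 <- run_grid(segs, methods = "HT", kinds = "SDC", n_folds = 4,
                 seed = 9)
  g2 <- run_grid(segs, methods = "HT", kinds = "SDC", n_folds = 4,
                 seed = 9)
  expect_identical(g1$folds, g2$folds)
})
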