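#' Confusion counts for binary CVD detection
#'
#' CVD is the positive class: `tp` counts CVD segments predicted CVD, `fn`
#' CVD predicted NORMAL, `fp` NORMAL predicted CVD, `tn` NORMAL predicted
#' NORMAL.
#'
#' @param truth,pred Equal-length character vectors of `"CVD"` /
#'   `"NORMAL"`.
#' @return An object of class `confusion_counts` (named integer list).
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred)) stop_ppg("length mismatch")
  check_label(truth)
  check_label(pred)
  structure(list(
    tp = sum(truth == "CVD" & pred == "CVD"),
    tn = sum(truth == "NORMAL" & pred == "NORMAL"),
    fp = sum(truth == "NORMAL" & pred == "CVD"),
    fn = sum(truth == "CVD" & pred == "NORMAL")),
    class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("tp=%d tn=%d fp=%d fn=%d\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Confusion-matrix metric suite
#'
#' Computes, in percent: performance index
#' `PI = (TP + TN - FN - FP) / (TP + TN) * 100`, sensitivity
#' `TP / (TP + FN) * 100`, specificity `TN / (TN + FP) * 100`, accuracy
#' `(TP + TN) / total * 100`, good detection rate
#' `GDR = (TP + TN - FP) / (TP + TN + FN) * 100`, and the error rate,
#' reported as `100 - accuracy` so that accuracy and error always sum to
#' 100 exactly. A zero denominator makes the corresponding metric `NA`
#' with a warning.
#'
#' @param counts A [confusion_counts()] object, or a list with `tp`, `tn`,
#'   `fp`, `fn`.
#' @return Named list: `pi`, `sensitivity`, `specificity`, `accuracy`,
#'   `gdr`, `error_rate`.
#' @examples
#' classification_metrics(list(tp = 14400, tn = 14400, fp = 720, fn = 0))
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp
  tn <- counts$tn
  fp <- counts$fp
  fn <- counts$fn
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NA_real_)
    }
    100 * num / den
  }
  acc <- safe(tp + tn, total, "accuracy")
  list(pi = safe(tp + tn - fn - fp, tp + tn, "performance index"),
       sensitivity = safe(tp, tp + fn, "sensitivity"),
       specificity = safe(tn, tn + fp, "specificity"),
       accuracy = acc,
       gdr = safe(tp + tn - fp, tp + tn + fn, "good detection rate"),
       error_rate = if (is.na(acc)) NA_real_ else 100 - acc)
}

#' Stratified fold assignment for segment-level cross-validation
#'
#' Assigns each row to one of `n_folds` folds, stratified by class (the
#' default, mirroring segment-level evaluation) or by subject (the honest
#' generalization test: all segments of a subject share a fold).
#'
#' @param y Character class labels per segment.
#' @param subject Subject id per segment (used when
#'   `subject_level = TRUE`).
#' @param n_folds Number of folds (default 10, i.e. 90/10 splits).
#' @param subject_level Keep subjects intact across folds?
#' @param seed Integer seed.
#' @return Integer fold id per row.
#' @export
make_folds <- function(y, subject = NULL, n_folds = 10,
                       subject_level = FALSE, seed = 1L) {
  stopifnot(n_folds >= 2)
  n <- length(y)
  fold <- integer(n)
  with_seed(seed, {
    if (subject_level) {
      stopifnot(!is.null(subject))
      for (cl in unique(y)) {
        subs <- unique(subject[y == cl])
        f <- rep_len(seq_len(n_folds), length(subs))[sample.int(length(subs))]
        for (i in seq_along(subs)) {
          fold[subject == subs[i]] <- f[i]
        }
      }
    } else {
      for (cl in unique(y)) {
        idx <- which(y == cl)
        fold[idx] <- rep_len(seq_len(n_folds),
                             length(idx))[sample.int(length(idx))]
      }
    }
  })
  fold
}

#' Run the reduction-method x classifier evaluation grid
#'
#' For each requested reduction method the cohort's pooled segments are
#' reduced once, then each classifier is evaluated under stratified 10-fold
#' cross-validation (per fold: fit on 90% of segments, evaluate on 10%).
#' Reports per-fold and fold-averaged confusion counts and metrics, plus
#' the per-class test MSE of the scores against the coded targets. Folds
#' whose training part holds a single class are skipped with a warning and
#' recorded.
#'
#' @param seg_list List of segment matrices (see [segment_record()]).
#' @param methods Character subset of
#'   `c("HT", "NLR", "ABC_PSO", "CUCKOO", "DRAGONFLY")`.
#' @param kinds Character subset of the twelve classifier names.
#' @param n_folds Number of folds.
#' @param coding,stop Passed to [ppg_classifier()].
#' @param swarm Passed to the mask-based reducers.
#' @param classifier_params Named list of per-kind parameter overrides,
#'   e.g. `list(SDC = list(lambda = 1))`.
#' @param subject_level Subject-level folds instead of segment-level.
#' @param seed Master seed for fold assignment and the seeded classifiers.
#' @return An object of class `ppg_grid`: list with `folds` (per-fold data
#'   frame), `summary` (fold-averaged data frame) and `skipped`.
#' @export
run_grid <- function(seg_list, methods = c("HT", "NLR"),
                     kinds = c("PCA", "BLDC", "SDC"), n_folds = 10,
                     coding = target_coding(), stop = stop_rule(),
                     swarm = swarm_params(), classifier_params = list(),
                     subject_level = FALSE, seed = 1L) {
  stopifnot(length(methods) >= 1, length(kinds) >= 1)
  kinds <- vapply(kinds, function(k) match.arg(toupper(k),
                                               classifier_kinds()),
                  character(1))
  pooled0 <- pool_segments(seg_list)
  fold <- make_folds(pooled0$y, pooled0$subject, n_folds,
                     subject_level, child_seed(seed, 11))
  rows <- list()
  skipped <- list()
  for (method in methods) {
    sw <- swarm
    sw$seed <- child_seed(seed, match(method, c("HT", "NLR", "ABC_PSO",
                                                "CUCKOO", "DRAGONFLY")))
    fm_list <- reduce_features(seg_list, method, params = sw)
    x <- do.call(rbind, lapply(fm_list, `[[`, "features"))
    y <- pooled0$y
    for (kind in kinds) {
      prm <- classifier_params[[kind]]
      if (is.null(prm)) prm <- list()
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 1 ||
            sum(!tr) == 0) {
          warning(sprintf("fold %d for %s/%s skipped (single class)",
                          f, method, kind))
          skipped[[length(skipped) + 1]] <-
            list(method = method, kind = kind, fold = f)
          next
        }
        model <- ppg_classifier(x[tr, , drop = FALSE], y[tr], kind,
                                coding = coding, stop = stop, params = prm,
                                seed = child_seed(seed, 100 * f +
                                                    match(kind,
                                                          classifier_kinds())))
        sc <- predict(model, x[!tr, , drop = FALSE], type = "score")
        pred <- ifelse(sc >= model$threshold, "CVD", "NORMAL")
        cc <- confusion_counts(y[!tr], pred)
        met <- classification_metrics(cc)
        coded_test <- code_targets(y[!tr], coding)
        is_c <- y[!tr] == "CVD"
        rows[[length(rows) + 1]] <- data.frame(
          method = method, classifier = kind, fold = f,
          tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
          pi = met$pi, sensitivity = met$sensitivity,
          specificity = met$specificity, accuracy = met$accuracy,
          gdr = met$gdr, error_rate = met$error_rate,
          mse_cvd = if (any(is_c)) {
            training_mse(sc[is_c], coded_test[is_c])
          } else {
            NA_real_
          },
          mse_normal = if (any(!is_c)) {
            training_mse(sc[!is_c], coded_test[!is_c])
          } else {
            NA_real_
          },
          n_test = sum(!tr))
      }
    }
  }
  folds_df <- do.call(rbind, rows)
  metric_cols <- c("pi", "sensitivity", "specificity", "accuracy", "gdr",
                   "error_rate", "mse_cvd", "mse_normal")
  agg <- stats::aggregate(folds_df[metric_cols],
                          by = folds_df[c("method", "classifier")],
                          FUN = function(v) mean(v, na.rm = TRUE))
  agg <- agg[order(agg$method, match(agg$classifier, classifier_kinds())), ]
  rownames(agg) <- NULL
  structure(list(folds = folds_df, summary = agg, skipped = skipped,
                 n_folds = n_folds, seed = seed),
            class = "ppg_grid")
}

#' @export
print.ppg_grid <- function(x, ...) {
  cat(sprintf("Evaluation grid: %d method x classifier cells, %d folds\n",
              nrow(x$summary), x$n_folds))
  print(x$summary[, c("method", "classifier", "accuracy", "gdr",
                      "error_rate")], digits = 4)
  if (length(x$skipped) > 0) {
    cat(length(x$skipped), "fold(s) skipped\n")
  }
  invisible(x)
}
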