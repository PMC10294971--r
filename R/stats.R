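#' Sample moments of a collection of values
#'
#' Mean, sample variance (n - 1 denominator), Fisher skewness and excess
#' kurtosis (a normal sample gives skewness and kurtosis near 0). With zero
#' variance the shape moments are undefined and returned as `NA` with a
#' `flagged` marker.
#'
#' @param values Numeric vector, at least 2 values (4 for kurtosis).
#' @return Named list: `mean`, `variance`, `skewness`, `kurtosis`,
#'   `flagged`.
#' @examples
#' feature_moments(c(1, 2, 3, 4, 5))  # mean 3, variance 2.5
#' @export
feature_moments <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop_ppg("need at least 2 finite values")
  mu <- mean(values)
  v <- stats::var(values)
  if (v <= 0) {
    return(list(mean = mu, variance = 0, skewness = NA_real_,
                kurtosis = NA_real_, flagged = TRUE))
  }
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  skew <- m3 / m2^1.5
  kurt <- if (n >= 4) mean((values - mu)^4) / m2^2 - 3 else NA_real_
  list(mean = mu, variance = v, skewness = skew, kurtosis = kurt,
       flagged = FALSE)
}

#' Mean within-class Pearson correlation over segment pairs
#'
#' Averages the Pearson correlation coefficient over distinct pairs of
#' segment feature rows, a summary of how mutually correlated the reduced
#' segments of one class are. Pair count is capped (seeded subsample) for
#' tractability; zero-variance segments are excluded with a warning.
#'
#' @param fm A feature matrix object, or a plain numeric matrix of rows.
#' @param max_pairs Cap on sampled pairs.
#' @param seed Seed for the pair subsample.
#' @return Mean pairwise correlation in `[-1, 1]`.
#' @export
pairwise_pcc <- function(fm, max_pairs = 10000, seed = 1L) {
  x <- if (inherits(fm, "feature_matrix")) fm$features else fm
  check_finite_matrix(x, "features")
  if (nrow(x) < 2) stop_ppg("need at least 2 segments")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance segment(s) excluded")
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) < 2) stop_ppg("fewer than 2 non-degenerate segments")
  }
  n <- nrow(x)
  n_pairs <- n * (n - 1) / 2
  if (n_pairs <= max_pairs) {
    cm <- stats::cor(t(x))
    return(mean(cm[upper.tri(cm)]))
  }
  with_seed(seed, {
    i <- sample.int(n, max_pairs, replace = TRUE)
    j <- sample.int(n, max_pairs, replace = TRUE)
    ok <- i != j
    i <- i[ok]
    j <- j[ok]
    mean(vapply(seq_along(i),
                function(k) stats::cor(x[i[k], ], x[j[k], ]), numeric(1)))
  })
}

#' Sample entropy of a sequence
#'
#' `SampEn(m, r)` is `-log(A / B)`, where `B` counts pairs of length-`m`
#' templates within Chebyshev distance `r * sd(x)` of each other and `A`
#' counts the same at length `m + 1`; self-matches are excluded. Lower
#' values mean a more regular, predictable sequence. If either count is
#' zero the entropy is undefined and `Inf` is returned with a warning.
#'
#' @param x Numeric vector, length >= m + 2.
#' @param m Template length (default 2).
#' @param r Tolerance in units of the standard deviation of `x`
#'   (default 0.2).
#' @return Sample entropy in nats.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2) {
  stopifnot(is.numeric(x), m >= 1, r > 0)
  n <- length(x)
  if (n < m + 2) stop_ppg("need length >= m + 2")
  sdx <- stats::sd(x)
  tol <- if (sdx > 0) r * sdx else r
  # both template lengths use the first n - m templates (standard SampEn
  # convention), pairwise Chebyshev distance built up per offset
  count_matches <- function(mm) {
    n_t <- n - m
    d <- matrix(0, n_t, n_t)
    for (k in 0:(mm - 1)) {
      v <- x[(1 + k):(n_t + k)]
      d <- pmax(d, abs(outer(v, v, `-`)))
    }
    (sum(d <= tol) - n_t) / 2                  # exclude self-matches
  }
  B <- count_matches(m)
  A <- count_matches(m + 1)
  if (A == 0 || B == 0) {
    warning("no template matches; sample entropy undefined (Inf)")
    return(Inf)
  }
  -log(A / B)
}

#' First canonical correlation between two class feature sets
#'
#' Measures the strongest linear association between the feature columns of
#' two classes, via ridge-regularized whitening of the within-set
#' covariances followed by an SVD of the cross-covariance. Invariant to
#' invertible linear transforms of either set (hence to column
#' permutations). Rank deficiency is handled by the ridge; the estimate is
#' clipped to `[0, 1]`.
#'
#' @param xa,xb Numeric matrices with a common column count and >= 2 rows
#'   each. Row counts may differ; rows are paired up to the shorter of the
#'   two (extra rows are ignored for the cross term).
#' @param ridge Regularization added to the covariance diagonals, as a
#'   fraction of the mean diagonal.
#' @return First canonical correlation in `[0, 1]`.
#' @export
cca_first <- function(xa, xb, ridge = 1e-6) {
  check_finite_matrix(xa, "xa")
  check_finite_matrix(xb, "xb")
  if (ncol(xa) != ncol(xb)) stop_ppg("column counts differ")
  if (nrow(xa) < 2 || nrow(xb) < 2) stop_ppg("need >= 2 rows per class")
  n <- min(nrow(xa), nrow(xb))
  xa <- scale(xa[seq_len(n), , drop = FALSE], scale = FALSE)
  xb <- scale(xb[seq_len(n), , drop = FALSE], scale = FALSE)
  saa <- crossprod(xa) / (n - 1)
  sbb <- crossprod(xb) / (n - 1)
  sab <- crossprod(xa, xb) / (n - 1)
  reg <- function(s) s + diag(ridge * mean(diag(s)) + 1e-12, nrow(s))
  inv_sqrt <- function(s) {
    e <- eigen(reg(s), symmetric = TRUE)
    vals <- pmax(e$values, max(e$values) * 1e-12)
    e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
  }
  m <- inv_sqrt(saa) %*% sab %*% inv_sqrt(sbb)
  min(1, max(0, svd(m)$d[1]))
}

#' Descriptor panel for a set of reduced cohorts
#'
#' Computes, per reduction method and class, the average of the per-subject
#' mean, variance, skewness and excess kurtosis of the pooled feature
#' values, the mean within-class pairwise segment correlation, the average
#' per-subject sample entropy (computed on a length-capped subsequence of
#' the pooled features), and the first canonical correlation between the
#' two class feature sets.
#'
#' @param fm_list List of feature matrix objects (one per subject), all
#'   from the same reduction method.
#' @param sampen_cap Maximum sequence length used for sample entropy.
#' @param seed Seed for the correlation pair subsample.
#' @return A data frame with one row per statistic and columns for the two
#'   classes, plus a `cca` attribute.
#' @export
stats_summary <- function(fm_list, sampen_cap = 1000, seed = 1L) {
  stopifnot(length(fm_list) >= 2)
  labels <- vapply(fm_list, `[[`, character(1), "label")
  per_class <- function(cl) {
    fms <- fm_list[labels == cl]
    if (length(fms) == 0) return(rep(NA_real_, 6))
    mom <- vapply(fms, function(f) {
      m <- feature_moments(as.vector(f$features))
      c(m$mean, m$variance, m$skewness, m$kurtosis)
    }, numeric(4))
    se <- vapply(fms, function(f) {
      v <- as.vector(t(f$features))
      if (length(v) > sampen_cap) {
        v <- v[unique(round(seq(1, length(v), length.out = sampen_cap)))]
      }
      sample_entropy(v)
    }, numeric(1))
    pcc <- pairwise_pcc(do.call(rbind, lapply(fms, `[[`, "features")),
                        seed = seed)
    c(rowMeans(mom), pcc, mean(se[is.finite(se)]))
  }
  cvd <- per_class("CVD")
  nrm <- per_class("NORMAL")
  out <- data.frame(
    statistic = c("mean", "variance", "skewness", "kurtosis", "pcc",
                  "sample_entropy"),
    NORMAL = nrm, CVD = cvd)
  xa <- do.call(rbind, lapply(fm_list[labels == "CVD"], `[[`, "features"))
  xb <- do.call(rbind, lapply(fm_list[labels == "NORMAL"], `[[`, "features"))
  attr(out, "cca") <- if (!is.null(xa) && !is.null(xb)) {
    cca_first(xa, xb)
  } else {
    NA_real_
  }
  attr(out, "kurtosis_convention") <- "excess"
  out
}

#' Normal-probability plot of reduced feature values
#'
#' Thin wrapper over [stats::qqnorm()] / [stats::qqline()] for eyeballing
#' non-Gaussianity and outliers in a subject's reduced features.
#'
#' @param fm A feature matrix object or numeric vector/matrix.
#' @param ... Passed to [stats::qqnorm()].
#' @return Invisibly, the qqnorm coordinates.
#' @export
plot_normal_probability <- function(fm, ...) {
  v <- if (inherits(fm, "feature_matrix")) as.vector(fm$features)
       else as.vector(fm)
  q <- stats::qqnorm(v, ...)
  stats::qqline(v)
  invisible(q)
}
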