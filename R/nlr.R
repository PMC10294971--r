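#' Fit a sum-of-Gaussians nonlinear regression to one segment
#'
#' Models a segment as `f(t, phi) = sum_g A_g exp(-(t - c_g)^2 / (2 w_g^2))`
#' on the normalized time axis `t in [0, 1]` and fits `phi = (A, c, w)` by
#' Levenberg-Marquardt least squares, minimizing the residual sum of
#' squares. Three starts with kernel centers spread across the segment are
#' tried and the lowest-RSS fit kept; if no start converges the best iterate
#' is returned with `converged = FALSE`.
#'
#' @param segment Finite real vector, length >= `3 * n_kernels`.
#' @param n_kernels Number of Gaussian kernels (>= 1); the default of 4
#'   gives the two-lobe pulse morphology headroom for asymmetry.
#' @return List with `par` (named vector `A1..`, `c1..`, `w1..`), `rss`,
#'   `fitted`, and `converged`.
#' @export
nlr_fit <- function(segment, n_kernels = 4) {
  stopifnot(n_kernels >= 1)
  if (!is.numeric(segment) || any(!is.finite(segment))) {
    stop_ppg("segment must be a finite numeric vector")
  }
  n <- length(segment)
  if (n < 3 * n_kernels) {
    stop_ppg("segment length must be >= 3 * n_kernels")
  }
  tt <- seq(0, 1, length.out = n)
  model <- function(par, t) {
    A <- par[seq_len(n_kernels)]
    cc <- par[n_kernels + seq_len(n_kernels)]
    w <- par[2 * n_kernels + seq_len(n_kernels)]
    f <- numeric(length(t))
    for (g in seq_len(n_kernels)) {
      f <- f + A[g] * exp(-(t - cc[g])^2 / (2 * w[g]^2))
    }
    f
  }
  resid_fn <- function(par) segment - model(par, tt)
  amp0 <- max(abs(segment))
  if (amp0 == 0) amp0 <- 1
  centers <- seq(0.1, 0.9, length.out = n_kernels)
  starts <- list(
    c(rep(amp0 * 0.8, n_kernels), centers, rep(0.1, n_kernels)),
    c(rep(amp0 * 0.5, n_kernels), pmin(0.95, centers + 0.1),
      rep(0.05, n_kernels)),
    c(rep(amp0, n_kernels), pmax(0.05, centers - 0.05), rep(0.2, n_kernels))
  )
  lower <- c(rep(-2 * amp0, n_kernels), rep(-0.2, n_kernels),
             rep(0.005, n_kernels))
  upper <- c(rep(2 * amp0, n_kernels), rep(1.2, n_kernels),
             rep(5, n_kernels))   # wide kernels approximate constants
  best <- NULL
  any_conv <- FALSE
  for (st in starts) {
    # nls.lm warns when maxiter is hit; convergence is surfaced through
    # the `converged` flag instead
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                           fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 100, ptol = 1e-10, ftol = 1e-10))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:4
    any_conv <- any_conv || conv
    if (is.null(best) || rss < best$rss) {
      best <- list(par = fit$par, rss = rss)
    }
  }
  if (is.null(best)) stop_ppg("all Levenberg-Marquardt starts failed")
  names(best$par) <- c(paste0("A", seq_len(n_kernels)),
                       paste0("c", seq_len(n_kernels)),
                       paste0("w", seq_len(n_kernels)))
  list(par = best$par, rss = best$rss,
       fitted = model(best$par, tt), converged = any_conv)
}

#' Reduce segments to 100 features by nonlinear-regression curve fitting
#'
#' Fits the sum-of-Gaussians model of [nlr_fit()] to each segment and
#' evaluates the fitted curve at 100 equispaced time points spanning the
#' segment, giving a smooth 100-feature summary of the pulse shape.
#'
#' @inheritParams ht_reduce
#' @param n_kernels Passed to [nlr_fit()].
#' @return A feature matrix object (`n_segments x 100`, method `"NLR"`).
#' @export
nlr_reduce <- function(seg, n_kernels = 4) {
  stopifnot(inherits(seg, "segment_matrix"))
  n <- ncol(seg$segments)
  t_out <- seq(0, 1, length.out = 100)
  feats <- t(apply(seg$segments, 1, function(s) {
    fit <- nlr_fit(s, n_kernels)
    A <- fit$par[seq_len(n_kernels)]
    cc <- fit$par[n_kernels + seq_len(n_kernels)]
    w <- fit$par[2 * n_kernels + seq_len(n_kernels)]
    f <- numeric(100)
    for (g in seq_len(n_kernels)) {
      f <- f + A[g] * exp(-(t_out - cc[g])^2 / (2 * w[g]^2))
    }
    f
  }))
  feature_matrix(seg$subject_id, feats, seg$label, "NLR",
                 list(n_kernels = n_kernels))
}
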