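#' Regression target coding for the two classes
#'
#' Score-producing classifiers are trained against real-valued targets:
#' CVD segments are coded `t_cvd` and NORMAL segments `t_normal`, with the
#' gap constraint `|t_cvd - t_normal| >= 0.5`. Defaults 0.85 / 0.1.
#'
#' @param t_cvd Target for the CVD class, in `(0, 1]`.
#' @param t_normal Target for the NORMAL class, in `[0, 1)`.
#' @return An object of class `target_coding`.
#' @export
target_coding <- function(t_cvd = 0.85, t_normal = 0.1) {
  stopifnot(t_cvd > 0, t_cvd <= 1, t_normal >= 0, t_normal < 1)
  if (abs(t_cvd - t_normal) < 0.5) {
    stop_ppg("|t_cvd - t_normal| must be >= 0.5; got ",
             abs(t_cvd - t_normal))
  }
  structure(list(t_cvd = t_cvd, t_normal = t_normal),
            class = "target_coding")
}

#' Map class labels to coded regression targets
#'
#' @param labels Character vector of `"CVD"` / `"NORMAL"`.
#' @param coding A [target_coding()].
#' @return Numeric vector of coded targets.
#' @examples
#' code_targets(c("CVD", "NORMAL"))  # 0.85 0.10
#' @export
code_targets <- function(labels, coding = target_coding()) {
  check_label(labels)
  ifelse(labels == "CVD", coding$t_cvd, coding$t_normal)
}

#' Mean squared error between scores and coded targets
#'
#' @param scores,targets Equal-length numeric vectors.
#' @return Mean of squared differences.
#' @export
training_mse <- function(scores, targets) {
  if (length(scores) == 0) stop_ppg("empty input")
  if (length(scores) != length(targets)) stop_ppg("length mismatch")
  mean((scores - targets)^2)
}

#' Iteration stopping rule
#'
#' Iterative classifiers stop when the training criterion falls to
#' `mse_tol` or after `max_iter` iterations, whichever happens first.
#'
#' @param mse_tol Criterion tolerance (default `1e-5`).
#' @param max_iter Iteration cap (default 1000).
#' @return An object of class `stop_rule`.
#' @export
stop_rule <- function(mse_tol = 1e-5, max_iter = 1000) {
  stopifnot(mse_tol > 0, max_iter >= 1)
  structure(list(mse_tol = mse_tol, max_iter = as.integer(max_iter)),
            class = "stop_rule")
}

#' Detrended-fluctuation scaling exponent
#'
#' Computes the DFA exponent of a series: the mean-removed cumulative
#' profile is divided into non-overlapping windows of each size `n`, a
#' least-squares line is removed per window, the root-mean-square residual
#' `F(n)` is recorded, and the exponent is the least-squares slope of
#' `log F(n)` against `log n`. White noise gives roughly 0.5, Brownian
#' paths roughly 1.5. A perfectly linear profile makes `F(n)` vanish and
#' the exponent undefined (`NA` with a warning).
#'
#' @param series Numeric vector, length >= `2 * max(windows)`.
#' @param windows Integer window sizes (>= 3 sizes). Default: `{4, 8, 16,
#'   32}` for series of length >= 64, otherwise a geometric grid within
#'   `[3, length/2]`.
#' @return The scaling exponent, with the per-window fluctuations attached
#'   as attribute `"fn"`.
#' @export
dfa_exponent <- function(series, windows = NULL) {
  stopifnot(is.numeric(series), all(is.finite(series)))
  K <- length(series)
  if (is.null(windows)) windows <- default_dfa_windows(K)
  windows <- sort(unique(as.integer(windows)))
  if (length(windows) < 3) stop_ppg("need at least 3 window sizes")
  if (K < 2 * max(windows)) {
    stop_ppg("series length must be >= 2 * max(windows)")
  }
  fn <- dfa_fluctuations(matrix(series, 1), windows)[1, ]
  scale <- stats::sd(series) + 1e-300
  if (any(fn <= scale * 1e-10)) {
    warning("fluctuation function vanishes; exponent undefined")
    out <- NA_real_
    attr(out, "fn") <- fn
    return(out)
  }
  lx <- log(windows)
  ly <- log(fn)
  out <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  attr(out, "fn") <- fn
  out
}

default_dfa_windows <- function(K) {
  if (K >= 64) return(c(4L, 8L, 16L, 32L))
  w <- unique(pmax(3L, as.integer(round(exp(
    seq(log(3), log(max(4, K / 2)), length.out = 4))))))
  w[w <= K / 2]
}

# F(n) per row of a profile matrix built from `mat` rows; shared by
# dfa_exponent and the DFA-based classifiers.
dfa_fluctuations <- function(mat, windows) {
  K <- ncol(mat)
  prof <- t(apply(mat, 1, function(r) cumsum(r - mean(r))))
  if (nrow(mat) == 1) prof <- matrix(prof, 1)
  out <- matrix(NA_real_, nrow(mat), length(windows))
  for (wi in seq_along(windows)) {
    n <- windows[wi]
    nblk <- K %/% n
    tt <- seq_len(n)
    H <- cbind(1, tt)
    P <- diag(n) - H %*% solve(crossprod(H), t(H))   # residual projector
    ss <- numeric(nrow(mat))
    for (b in seq_len(nblk)) {
      idx <- ((b - 1) * n + 1):(b * n)
      res <- prof[, idx, drop = FALSE] %*% P
      ss <- ss + rowSums(res^2)
    }
    out[, wi] <- sqrt(ss / (nblk * n))
  }
  out
}

dfa_alpha_rows <- function(mat, windows) {
  fn <- dfa_fluctuations(mat, windows)
  lx <- log(windows)
  lxc <- lx - mean(lx)
  apply(fn, 1, function(f) {
    if (any(f <= 1e-300)) return(NA_real_)
    ly <- log(f)
    sum(lxc * (ly - mean(ly))) / sum(lxc^2)
  })
}

# Remove per-window least-squares lines from each row (the DFA detrending
# operator applied to the feature vector itself).
detrend_rows <- function(mat, window = NULL) {
  p <- ncol(mat)
  if (is.null(window)) window <- max(4L, p %/% 4L)
  out <- mat
  starts <- seq(1, p, by = window)
  for (s in starts) {
    idx <- s:min(p, s + window - 1)
    if (length(idx) < 3) {
      out[, idx] <- 0
      next
    }
    tt <- seq_along(idx)
    H <- cbind(1, tt)
    P <- diag(length(idx)) - H %*% solve(crossprod(H), t(H))
    out[, idx] <- mat[, idx, drop = FALSE] %*% P
  }
  out
}

## ------------------------------------------------------------------
## shared internals

firefly_attractiveness <- function(r, alpha0 = 0.65, beta = 1) {
  alpha0 * exp(-beta * r^2)
}

# Diagonal-covariance Gaussian mixture fitted by EM. The log-likelihood
# trace is asserted non-decreasing on every fit.
em_diag <- function(x, Z, stop, seed) {
  n <- nrow(x)
  p <- ncol(x)
  var_floor <- pmax(apply(x, 2, stats::var) * 1e-4, 1e-10)
  with_seed(seed, {
    centers <- x[sample.int(n, Z), , drop = FALSE]
    log_dens <- function(mu, v) {
      # n x Z matrix of log N(x | mu_z, diag(v_z))
      vapply(seq_len(Z), function(z) {
        -0.5 * rowSums(sweep(sweep(x, 2, mu[z, ])^2, 2, v[z, ], `/`)) -
          0.5 * sum(log(2 * pi * v[z, ]))
      }, numeric(n))
    }
    mu <- centers
    v <- matrix(rep(pmax(apply(x, 2, stats::var), var_floor), each = Z),
                Z, p, byrow = FALSE)
    pi_z <- rep(1 / Z, Z)
    ll_trace <- numeric(0)
    resp <- NULL
    for (it in seq_len(stop$max_iter)) {
      ld <- sweep(log_dens(mu, v), 2, log(pi_z), `+`)
      m <- apply(ld, 1, max)
      lse <- m + log(rowSums(exp(ld - m)))
      ll <- sum(lse)
      resp <- exp(ld - lse)
      if (length(ll_trace) > 0) {
        last <- ll_trace[length(ll_trace)]
        stopifnot(ll >= last - 1e-6 * (abs(last) + 1))
        if (abs(ll - last) < stop$mse_tol * (abs(last) + 1)) {
          ll_trace <- c(ll_trace, ll)
          break
        }
      }
      ll_trace <- c(ll_trace, ll)
      nk <- colSums(resp) + 1e-12
      pi_z <- nk / sum(nk)
      mu <- t(vapply(seq_len(Z), function(z) {
        colSums(x * resp[, z]) / nk[z]
      }, numeric(p)))
      v <- t(vapply(seq_len(Z), function(z) {
        pmax(colSums(sweep(x, 2, mu[z, ])^2 * resp[, z]) / nk[z], var_floor)
      }, numeric(p)))
    }
    list(pi = pi_z, mu = mu, var = v, loglik = ll_trace, resp = resp)
  })
}

em_diag_loglik <- function(model, x) {
  Z <- length(model$pi)
  n <- nrow(x)
  ld <- vapply(seq_len(Z), function(z) {
    -0.5 * rowSums(sweep(sweep(x, 2, model$mu[z, ])^2, 2,
                         model$var[z, ], `/`)) -
      0.5 * sum(log(2 * pi * model$var[z, ])) + log(model$pi[z])
  }, numeric(n))
  if (n == 1) ld <- matrix(ld, 1)
  m <- apply(ld, 1, max)
  list(lse = m + log(rowSums(exp(ld - m))), comp = ld)
}

# Nearest-prototype coded-target MSE: the shared objective of the firefly
# and harmony classifiers (prototype pair packed as c(proto_cvd, proto_n)).
prototype_mse <- function(w, x, coded, coding) {
  p <- ncol(x)
  d_c <- rowSums(sweep(x, 2, w[seq_len(p)])^2)
  d_n <- rowSums(sweep(x, 2, w[p + seq_len(p)])^2)
  pred <- ifelse(d_c <= d_n, coding$t_cvd, coding$t_normal)
  mean((pred - coded)^2)
}

prototype_score <- function(w, x, coding) {
  p <- ncol(x)
  d_c <- rowSums(sweep(x, 2, w[seq_len(p)])^2)
  d_n <- rowSums(sweep(x, 2, w[p + seq_len(p)])^2)
  coding$t_normal + (coding$t_cvd - coding$t_normal) *
    sigmoid((d_n - d_c) / p)
}

knn_scores <- function(ref_x, ref_y, newx, k) {
  d <- outer(rowSums(newx^2), rowSums(ref_x^2), `+`) -
    2 * newx %*% t(ref_x)
  apply(d, 1, function(row) {
    nb <- order(row)[seq_len(k)]
    mean(ref_y[nb] == "CVD")
  })
}

sdc_class_score <- function(refs, newx, lambda) {
  d <- outer(rowSums(newx^2), rowSums(refs^2), `+`) - 2 * newx %*% t(refs)
  d[d < 0] <- 0
  apply(-lambda * d, 1, logsumexp)
}

stratified_subsample <- function(x, y, per_class, seed) {
  with_seed(seed, {
    keep <- unlist(lapply(unique(y), function(cl) {
      idx <- which(y == cl)
      if (length(idx) > per_class) sample(idx, per_class) else idx
    }))
    sort(keep)
  })
}

default_params <- function(kind) {
  switch(kind,
    PCA = list(threshold = 0.72),
    EM = list(),
    LOGREG = list(learning_rate = NULL),
    GMM = list(n_components = 2),
    BLDC = list(prior = 0.5, decision_threshold = 0, shrinkage = 0.05),
    FIREFLY = list(pop_size = 15, gamma = 0.1, alpha0 = 0.65, beta = 1,
                   stagnation = 25),
    HARMONY = list(memory_size = 12, hmcr = 0.9, par = 0.3,
                   bandwidth = 0.004, stagnation = 200),
    DFA = list(windows = NULL),
    PAC_BAYES = list(temperature = 4,
                     quantiles = seq(0.1, 0.9, by = 0.1)),
    KNN_PAC = list(k_grid = c(3, 5, 7), max_ref = 1000,
                   temperature = 4, quantiles = seq(0.1, 0.9, by = 0.1)),
    SDC = list(lambda = 0.5, max_ref = 500),
    DETREND_SDC = list(lambda = 0.5, max_ref = 500, window = NULL),
    stop_ppg("unknown classifier kind: ", kind))
}

#' The twelve classifier kind names
#'
#' @return Character vector of the classifier kinds accepted by
#'   [ppg_classifier()].
#' @export
classifier_kinds <- function() {
  c("PCA", "EM", "LOGREG", "GMM", "BLDC", "FIREFLY", "HARMONY", "DFA",
    "PAC_BAYES", "KNN_PAC", "SDC", "DETREND_SDC")
}

## ------------------------------------------------------------------
## per-kind fits; each returns list(fit = <kind-specific>, trace = <mse>)

fit_pca <- function(x, y, coded, coding, stop, prm, seed) {
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  v1 <- svd(xc, nu = 0, nv = 1)$v[, 1]
  proj <- drop(xc %*% v1)
  if (mean(proj[y == "CVD"]) < mean(proj[y == "NORMAL"])) v1 <- -v1
  proj <- drop(xc %*% v1)
  rng <- range(proj)
  if (diff(rng) == 0) rng <- rng + c(-1, 1)
  list(center = ctr, axis = v1, range = rng)
}

score_pca <- function(fit, newx) {
  proj <- drop(sweep(newx, 2, fit$center) %*% fit$axis)
  pmin(1, pmax(0, (proj - fit$range[1]) / diff(fit$range)))
}

fit_em <- function(x, y, coded, coding, stop, prm, seed) {
  model <- em_diag(x, 2L, stop, seed)
  adv <- colMeans(model$resp[y == "CVD", , drop = FALSE]) -
    colMeans(model$resp[y == "NORMAL", , drop = FALSE])
  list(model = model, cvd_comp = which.max(adv),
       loglik = model$loglik)
}

score_em <- function(fit, newx) {
  ld <- em_diag_loglik(fit$model, newx)
  exp(ld$comp[, fit$cvd_comp] - ld$lse)
}

fit_logreg <- function(x, y, coded, coding, stop, prm, seed) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- cbind(1, sweep(sweep(x, 2, ctr), 2, scl, `/`))
  y01 <- as.numeric(y == "CVD")
  n <- nrow(xs)
  p <- ncol(xs)
  eta <- if (is.null(prm$learning_rate)) 4 / p else prm$learning_rate
  w <- numeric(p)
  trace <- numeric(0)
  for (it in seq_len(stop$max_iter)) {
    pr <- sigmoid(drop(xs %*% w))
    mse <- mean((pr - coded)^2)
    if (length(trace) > 0 && abs(trace[length(trace)] - mse) < 1e-12) {
      trace <- c(trace, mse)
      break
    }
    trace <- c(trace, mse)
    if (mse <= stop$mse_tol) break
    w <- w - eta * drop(crossprod(xs, pr - y01)) / n
  }
  list(w = w, center = ctr, scale = scl, trace = trace)
}

score_logreg <- function(fit, newx) {
  xs <- cbind(1, sweep(sweep(newx, 2, fit$center), 2, fit$scale, `/`))
  sigmoid(drop(xs %*% fit$w))
}

fit_gmm <- function(x, y, coded, coding, stop, prm, seed) {
  Z <- prm$n_components
  m_c <- em_diag(x[y == "CVD", , drop = FALSE], Z, stop,
                 child_seed(seed, 1))
  m_n <- em_diag(x[y == "NORMAL", , drop = FALSE], Z, stop,
                 child_seed(seed, 2))
  list(cvd = m_c, normal = m_n, p = ncol(x),
       loglik = list(cvd = m_c$loglik, normal = m_n$loglik))
}

score_gmm <- function(fit, newx) {
  llr <- (em_diag_loglik(fit$cvd, newx)$lse -
            em_diag_loglik(fit$normal, newx)$lse) / fit$p
  sigmoid(llr)
}

fit_bldc <- function(x, y, coded, coding, stop, prm, seed) {
  mu_c <- colMeans(x[y == "CVD", , drop = FALSE])
  mu_n <- colMeans(x[y == "NORMAL", , drop = FALSE])
  xc <- rbind(sweep(x[y == "CVD", , drop = FALSE], 2, mu_c),
              sweep(x[y == "NORMAL", , drop = FALSE], 2, mu_n))
  S <- crossprod(xc) / (nrow(xc) - 2)
  # shrink toward a scaled identity: pooled covariances of strongly
  # correlated feature panels are ill-conditioned at n comparable to p
  S <- (1 - prm$shrinkage) * S +
    prm$shrinkage * diag(mean(diag(S)) + 1e-12, nrow(S))
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv)) {
    warning("singular pooled covariance; ridge-regularized")
    S <- S + diag(mean(diag(S)) * 1e-4 + 1e-12, nrow(S))
    Sinv <- solve(S)
  }
  list(mu_c = mu_c, mu_n = mu_n, Sinv = Sinv,
       D = prm$decision_threshold)
}

score_bldc <- function(fit, newx) {
  w <- fit$Sinv %*% (fit$mu_c - fit$mu_n)
  mid <- (fit$mu_c + fit$mu_n) / 2
  delta <- drop(sweep(newx, 2, mid) %*% w) - fit$D
  sigmoid(delta)
}

fit_firefly <- function(x, y, coded, coding, stop, prm, seed) {
  p <- ncol(x)
  dim_w <- 2 * p
  obj <- function(w) prototype_mse(w, x, coded, coding)
  with_seed(seed, {
    pop <- prm$pop_size
    base <- c(colMeans(x[y == "CVD", , drop = FALSE]),
              colMeans(x[y == "NORMAL", , drop = FALSE]))
    spread <- stats::sd(x) + 1e-9
    W <- matrix(0, pop, dim_w)
    W[1, ] <- base
    for (i in 2:pop) W[i, ] <- base + stats::rnorm(dim_w, sd = spread)
    mse <- apply(W, 1, obj)
    gbest <- W[which.min(mse), ]
    gbest_mse <- min(mse)
    trace <- gbest_mse
    stagnant <- 0
    for (it in seq_len(stop$max_iter)) {
      if (gbest_mse <= stop$mse_tol || stagnant >= prm$stagnation) break
      bright <- 1 / (mse + 1e-12)
      for (t_i in seq_len(pop)) {
        for (s_i in seq_len(pop)) {
          if (bright[s_i] <= bright[t_i]) next
          r2 <- mean((W[t_i, ] - W[s_i, ])^2)
          att <- firefly_attractiveness(sqrt(r2), prm$alpha0, prm$beta)
          W[t_i, ] <- W[t_i, ] + att * (W[s_i, ] - W[t_i, ]) +
            prm$gamma * spread * stats::runif(dim_w, -1, 1)
        }
        mse[t_i] <- obj(W[t_i, ])
      }
      if (min(mse) < gbest_mse) {
        gbest <- W[which.min(mse), ]
        gbest_mse <- min(mse)
        stagnant <- 0
      } else {
        stagnant <- stagnant + 1
      }
      trace <- c(trace, gbest_mse)
    }
    list(w = gbest, trace = trace, coding = coding)
  })
}

score_firefly <- function(fit, newx) prototype_score(fit$w, newx, fit$coding)

fit_harmony <- function(x, y, coded, coding, stop, prm, seed) {
  p <- ncol(x)
  dim_w <- 2 * p
  obj <- function(w) prototype_mse(w, x, coded, coding)
  lo <- rep(apply(x, 2, min), 2)
  hi <- rep(apply(x, 2, max), 2)
  with_seed(seed, {
    hm_size <- prm$memory_size
    base <- c(colMeans(x[y == "CVD", , drop = FALSE]),
              colMeans(x[y == "NORMAL", , drop = FALSE]))
    spread <- stats::sd(x) + 1e-9
    HM <- matrix(0, hm_size, dim_w)
    HM[1, ] <- base
    for (i in 2:hm_size) {
      HM[i, ] <- if (i <= ceiling(hm_size / 2)) {
        base + stats::rnorm(dim_w, sd = spread)
      } else {
        stats::runif(dim_w, lo, hi)
      }
    }
    mse <- apply(HM, 1, obj)
    best <- which.min(mse)
    trace <- mse[best]
    stagnant <- 0
    for (it in seq_len(stop$max_iter)) {
      if (mse[best] <= stop$mse_tol || stagnant >= prm$stagnation) break
      new_h <- numeric(dim_w)
      use_mem <- stats::runif(dim_w) < prm$hmcr
      src <- sample.int(hm_size, dim_w, replace = TRUE)
      new_h <- HM[cbind(src, seq_len(dim_w))]
      pitch <- use_mem & (stats::runif(dim_w) < prm$par)
      new_h[pitch] <- new_h[pitch] +
        stats::runif(sum(pitch), -1, 1) * prm$bandwidth
      rnd <- !use_mem
      new_h[rnd] <- stats::runif(sum(rnd), lo[rnd], hi[rnd])
      new_mse <- obj(new_h)
      worst <- which.max(mse)
      if (new_mse < mse[worst]) {
        HM[worst, ] <- new_h
        mse[worst] <- new_mse
      }
      if (min(mse) < trace[length(trace)]) {
        stagnant <- 0
      } else {
        stagnant <- stagnant + 1
      }
      best <- which.min(mse)
      trace <- c(trace, mse[best])
    }
    list(w = HM[best, ], trace = trace, coding = coding)
  })
}

score_harmony <- score_firefly

fit_dfa <- function(x, y, coded, coding, stop, prm, seed) {
  windows <- if (is.null(prm$windows)) default_dfa_windows(ncol(x))
             else prm$windows
  alpha <- dfa_alpha_rows(x, windows)
  ok <- is.finite(alpha)
  mu_c <- mean(alpha[ok & y == "CVD"])
  mu_n <- mean(alpha[ok & y == "NORMAL"])
  s <- stats::sd(alpha[ok]) + 1e-6
  list(windows = windows, mu_c = mu_c, mu_n = mu_n, s = s)
}

score_dfa <- function(fit, newx) {
  alpha <- dfa_alpha_rows(newx, fit$windows)
  sc <- sigmoid((abs(alpha - fit$mu_n) - abs(alpha - fit$mu_c)) / fit$s)
  sc[!is.finite(sc)] <- 0.5
  sc
}

# Threshold-stump hypothesis space with a Gibbs posterior.
pac_stumps <- function(x, quantiles) {
  p <- ncol(x)
  stumps <- list()
  for (j in seq_len(p)) {
    th <- unique(stats::quantile(x[, j], quantiles, names = FALSE))
    for (t0 in th) {
      stumps[[length(stumps) + 1]] <- c(j, t0, 1)
      stumps[[length(stumps) + 1]] <- c(j, t0, -1)
    }
  }
  do.call(rbind, stumps)                      # columns: feature, cut, dir
}

stump_predict <- function(stumps, x) {
  # rows of x vs rows of stumps -> n x S logical (predicts CVD)
  vals <- x[, stumps[, 1], drop = FALSE]
  sweep(vals, 2, stumps[, 2]) * rep(stumps[, 3], each = nrow(x)) >= 0
}

fit_pac_bayes <- function(x, y, coded, coding, stop, prm, seed) {
  stumps <- pac_stumps(x, prm$quantiles)
  pred <- stump_predict(stumps, x)
  is_cvd <- y == "CVD"
  err <- colMeans(pred != is_cvd)
  logw <- -prm$temperature * nrow(x) * err
  logw <- logw - logsumexp(logw)
  list(stumps = stumps, log_posterior = logw)
}

score_pac_bayes <- function(fit, newx) {
  pred <- stump_predict(fit$stumps, newx)
  drop(pred %*% exp(fit$log_posterior))
}

fit_knn_pac <- function(x, y, coded, coding, stop, prm, seed) {
  pac <- fit_pac_bayes(x, y, coded, coding, stop, prm, seed)
  aug <- function(xx) cbind(xx, score_pac_bayes(pac, xx))
  xa <- aug(x)
  ctr <- colMeans(xa)
  scl <- apply(xa, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(xa, 2, ctr), 2, scl, `/`)
  keep <- if (nrow(xs) > 2 * prm$max_ref) {
    stratified_subsample(xs, y, prm$max_ref, child_seed(seed, 3))
  } else {
    seq_len(nrow(xs))
  }
  ref_x <- xs[keep, , drop = FALSE]
  ref_y <- y[keep]
  # deterministic stratified 80/20 validation split to pick k
  val <- logical(length(ref_y))
  for (cl in unique(ref_y)) {
    idx <- which(ref_y == cl)
    val[idx[idx %% 5 == 0]] <- TRUE
  }
  if (sum(val) < 2 || length(unique(ref_y[!val])) < 2) {
    k_best <- prm$k_grid[1]
  } else {
    acc <- vapply(prm$k_grid, function(k) {
      sc <- knn_scores(ref_x[!val, , drop = FALSE], ref_y[!val],
                       ref_x[val, , drop = FALSE], k)
      mean((sc >= 0.5) == (ref_y[val] == "CVD"))
    }, numeric(1))
    k_best <- prm$k_grid[which.max(acc)]
  }
  list(pac = pac, center = ctr, scale = scl, ref_x = ref_x, ref_y = ref_y,
       k = k_best)
}

score_knn_pac <- function(fit, newx) {
  xa <- cbind(newx, score_pac_bayes(fit$pac, newx))
  xs <- sweep(sweep(xa, 2, fit$center), 2, fit$scale, `/`)
  knn_scores(fit$ref_x, fit$ref_y, xs, fit$k)
}

fit_sdc <- function(x, y, coded, coding, stop, prm, seed) {
  keep <- if (nrow(x) > 2 * prm$max_ref) {
    stratified_subsample(x, y, prm$max_ref, child_seed(seed, 4))
  } else {
    seq_len(nrow(x))
  }
  list(refs_c = x[keep, , drop = FALSE][y[keep] == "CVD", , drop = FALSE],
       refs_n = x[keep, , drop = FALSE][y[keep] == "NORMAL", , drop = FALSE],
       lambda = prm$lambda)
}

score_sdc <- function(fit, newx) {
  q_c <- sdc_class_score(fit$refs_c, newx, fit$lambda)
  q_n <- sdc_class_score(fit$refs_n, newx, fit$lambda)
  sigmoid(q_c - q_n)
}

fit_detrend_sdc <- function(x, y, coded, coding, stop, prm, seed) {
  window <- if (is.null(prm$window)) max(4L, ncol(x) %/% 4L) else prm$window
  fit <- fit_sdc(detrend_rows(x, window), y, coded, coding, stop, prm, seed)
  fit$window <- window
  fit
}

score_detrend_sdc <- function(fit, newx) {
  score_sdc(fit, detrend_rows(newx, fit$window))
}

## ------------------------------------------------------------------

#' Fit one of the twelve segment classifiers
#'
#' All classifiers share one contract: fit on a feature matrix with
#' class labels coded to real targets (see [target_coding()]), emit a score
#' per segment, and threshold the score to a class label. The kinds are:
#' `PCA` (first-principal-axis projection, threshold 0.72), `EM`
#' (two-component latent-class EM on pooled features), `LOGREG` (gradient
#' logistic regression, threshold 0.5), `GMM` (one mixture per class,
#' likelihood-ratio score), `BLDC` (pooled-covariance Bayesian linear
#' discriminant, equal priors), `FIREFLY` and `HARMONY` (population
#' searches over class-prototype pairs minimizing the coded-target MSE),
#' `DFA` (per-segment detrended-fluctuation exponent, nearest class mean),
#' `PAC_BAYES` (Gibbs vote over single-feature threshold stumps),
#' `KNN_PAC` (k-nearest neighbours in the feature space augmented with the
#' PAC-Bayes score), `SDC` (softmax discriminant over squared distances,
#' lambda = 0.5) and `DETREND_SDC` (per-window linear detrending followed
#' by SDC). Iterative kinds honour the [stop_rule()]; randomized kinds are
#' deterministic given `seed`.
#'
#' @param x Numeric training matrix (rows = segments).
#' @param y Character labels (`"CVD"` / `"NORMAL"`), both classes present.
#' @param kind One of the twelve classifier names above.
#' @param coding A [target_coding()].
#' @param stop A [stop_rule()].
#' @param params Named list overriding the kind's default hyperparameters.
#' @param seed Integer seed for the randomized kinds.
#' @return An object of class `ppg_classifier` with elements `kind`,
#'   `fit`, `threshold`, `coding`, `train_mse` (criterion trace) and
#'   `train_scores`.
#' @examples
#' b <- generate_feature_blobs(50, 10, 6, seed = 2)
#' m <- ppg_classifier(b$x, b$y, "BLDC")
#' mean(predict(m, b$x) == b$y)
#' @export
ppg_classifier <- function(x, y, kind, coding = target_coding(),
                           stop = stop_rule(), params = list(),
                           seed = 1L) {
  kind <- match.arg(toupper(kind), classifier_kinds())
  x <- check_finite_matrix(x, "training features")
  check_label(y)
  stopifnot(length(y) == nrow(x))
  if (length(unique(y)) < 2) stop_ppg("training data must contain both classes")
  prm <- utils::modifyList(default_params(kind), params)
  coded <- code_targets(y, coding)
  fit_fun <- get(paste0("fit_", tolower(kind)), mode = "function")
  fit <- fit_fun(x, y, coded, coding, stop, prm, seed)
  threshold <- switch(kind,
                      PCA = prm$threshold,
                      LOGREG = 0.5,
                      FIREFLY = ,
                      HARMONY = (coding$t_cvd + coding$t_normal) / 2,
                      0.5)
  obj <- structure(list(kind = kind, fit = fit, threshold = threshold,
                        coding = coding, stop = stop, params = prm,
                        seed = seed, n_train = nrow(x), p = ncol(x)),
                   class = c(paste0("ppg_", tolower(kind)),
                             "ppg_classifier"))
  sc <- predict(obj, x, type = "score")
  obj$train_scores <- sc
  obj$train_mse <- if (!is.null(fit$trace)) fit$trace
                   else training_mse(sc, coded)
  obj
}

#' Predict scores or labels from a fitted classifier
#'
#' @param object A fitted [ppg_classifier()].
#' @param newx Numeric matrix with the training column count.
#' @param type `"label"` (default) or `"score"`.
#' @param ... Ignored.
#' @return Character labels, or numeric scores in `[0, 1]`. Labels are
#'   exactly `score >= threshold`.
#' @export
predict.ppg_classifier <- function(object, newx,
                                   type = c("label", "score"), ...) {
  type <- match.arg(type)
  newx <- check_finite_matrix(newx, "newx")
  if (ncol(newx) != object$p) {
    stop_ppg("newx has ", ncol(newx), " columns; model expects ", object$p)
  }
  score_fun <- get(paste0("score_", tolower(object$kind)),
                   mode = "function")
  sc <- as.numeric(score_fun(object$fit, newx))
  if (type == "score") return(sc)
  ifelse(sc >= object$threshold, "CVD", "NORMAL")
}

#' @export
print.ppg_classifier <- function(x, ...) {
  cat(sprintf("PPG segment classifier: %s\n", x$kind))
  cat(sprintf("  trained on %d segments x %d features\n", x$n_train, x$p))
  cat(sprintf("  score threshold %.4g; coded targets %.2f / %.2f\n",
              x$threshold, x$coding$t_cvd, x$coding$t_normal))
  cat(sprintf("  final training MSE %.4g (%d criterion evaluations)\n",
              x$train_mse[length(x$train_mse)], length(x$train_mse)))
  invisible(x)
}

#' @export
summary.ppg_classifier <- function(object, ...) {
  print(object)
  cat(sprintf("  training scores: min %.3f, median %.3f, max %.3f\n",
              min(object$train_scores),
              stats::median(object$train_scores),
              max(object$train_scores)))
  invisible(object)
}

#' Plot the training-score distribution of a fitted classifier
#'
#' Histogram of training scores with the decision threshold marked.
#'
#' @param x A fitted [ppg_classifier()].
#' @param ... Passed to [graphics::hist()].
#' @export
plot.ppg_classifier <- function(x, ...) {
  graphics::hist(x$train_scores, breaks = 30,
                 main = paste(x$kind, "training scores"),
                 xlab = "score", ...)
  graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}
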