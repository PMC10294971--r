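# Shared fixtures, built in code at test time.

tiny_cohort <- function(n_cvd = 2, n_normal = 2, duration = 30,
                        morphology_shift = 0.6, noise_sd = 0.05,
                        artifact_rate = 0, seed = 11) {
  generate_cohort(cohort_spec(n_cvd = n_cvd, n_normal = n_normal,
                              duration = duration,
                              morphology_shift = morphology_shift,
                              noise_sd = noise_sd,
                              artifact_rate = artifact_rate, seed = seed))
}

# Two-class data with 100 planted informative columns among 200.
planted_columns <- function(n_per = 150, delta = 0.5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  x <- matrix(rnorm(n * 200), n, 200)
  y <- rep(c("CVD", "NORMAL"), each = n_per)
  info <- sample(200, 100)
  x[y == "CVD", info] <- x[y == "CVD", info] + delta
  ord <- sample.int(n)
  list(x = x[ord, ], y = y[ord], info = info)
}

# Naive O(n^2 m) template-counting sample entropy, the brute-force oracle.
naive_sampen <- function(x, m = 2, r = 0.2) {
  n <- length(x)
  tol <- r * sd(x)
  count <- function(mm) {
    n_t <- n - m
    cnt <- 0
    for (i in seq_len(n_t - 1)) {
      for (j in (i + 1):n_t) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= tol) {
          cnt <- cnt + 1
        }
      }
    }
    cnt
  }
  -log(count(m + 1) / count(m))
}

# Nearest-centroid train/test accuracy, the Bayes-optimal oracle on
# identity-covariance Gaussian blobs.
centroid_accuracy <- function(x_tr, y_tr, x_te, y_te) {
  mu_c <- colMeans(x_tr[y_tr == "CVD", , drop = FALSE])
  mu_n <- colMeans(x_tr[y_tr == "NORMAL", , drop = FALSE])
  d_c <- rowSums(sweep(x_te, 2, mu_c)^2)
  d_n <- rowSums(sweep(x_te, 2, mu_n)^2)
  mean(ifelse(d_c <= d_n, "CVD", "NORMAL") == y_te)
}
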