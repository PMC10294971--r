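#' Specification of a synthetic two-class PPG cohort
#'
#' Describes the shape and statistical properties of a synthetic cohort of
#' single-channel photoplethysmogram (PPG) recordings: 41 subjects of 720 s
#' sampled at 200 samples/s by default, so that each subject contributes
#' 144,000 samples and 720 one-second segments. The two classes (CVD and
#' NORMAL) share a two-lobe beat template (systolic peak plus dicrotic wave);
#' `morphology_shift` scales how far the CVD template and beat-interval
#' variability are displaced from the NORMAL ones, so it acts as a class
#' separability dial with 0 meaning the classes are identically distributed.
#'
#' @param n_cvd,n_normal Number of subjects in each class.
#' @param fs Sampling rate in samples/s.
#' @param duration Recording length per subject in seconds; `fs * duration`
#'   must be a whole number of samples.
#' @param heart_rate_mean Mean heart rate in beats/min, shared by both
#'   classes at `morphology_shift = 0`.
#' @param morphology_shift Class separability in `[0, 1]`. The CVD dicrotic
#'   amplitude is multiplied by `1 - 0.6 * morphology_shift`, the systolic
#'   width by `1 + 0.4 * morphology_shift`, and the beat-interval coefficient
#'   of variation by `1 + 0.5 * morphology_shift`.
#' @param noise_sd Standard deviation of additive white measurement noise, in
#'   signal units (the systolic peak has unit amplitude).
#' @param artifact_rate Expected motion-artifact bumps per minute.
#' @param seed Integer seed; the pair (spec, seed) fully determines the
#'   generated cohort.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_cvd = 20, n_normal = 21, fs = 200, duration = 720,
                        heart_rate_mean = 72, morphology_shift = 0.6,
                        noise_sd = 0.05, artifact_rate = 0.2, seed = 1L) {
  stopifnot(n_cvd >= 0, n_normal >= 0, fs > 0, duration > 0,
            heart_rate_mean > 0, noise_sd >= 0, artifact_rate >= 0)
  if (morphology_shift < 0 || morphology_shift > 1) {
    stop_ppg("morphology_shift must lie in [0, 1]")
  }
  n_samp <- fs * duration
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    stop_ppg("fs * duration must be an integer number of samples; got ",
             n_samp)
  }
  structure(list(n_cvd = as.integer(n_cvd), n_normal = as.integer(n_normal),
                 fs = fs, duration = duration,
                 heart_rate_mean = heart_rate_mean,
                 morphology_shift = morphology_shift, noise_sd = noise_sd,
                 artifact_rate = artifact_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic PPG cohort spec\n")
  cat(sprintf("  subjects: %d CVD + %d NORMAL\n", x$n_cvd, x$n_normal))
  cat(sprintf("  %g samples/s x %g s = %d samples/subject\n",
              x$fs, x$duration, as.integer(round(x$fs * x$duration))))
  cat(sprintf("  HR %g bpm, shift %g, noise sd %g, artifacts %g/min, seed %d\n",
              x$heart_rate_mean, x$morphology_shift, x$noise_sd,
              x$artifact_rate, x$seed))
  invisible(x)
}

# Two-lobe beat template evaluated on a phase grid u in [0, 1).
# Class-dependent displacement: CVD shrinks the dicrotic lobe and widens the
# systolic lobe proportionally to `shift`.
beat_template <- function(u, shift, cvd) {
  a1 <- 1
  a2 <- 0.5
  c1 <- 0.25
  c2 <- 0.58
  w1 <- 0.05
  w2 <- 0.16
  if (cvd) {
    a2 <- a2 * (1 - 0.6 * shift)
    w1 <- w1 * (1 + 0.4 * shift)
  }
  a1 * exp(-(u - c1)^2 / (2 * w1^2)) + a2 * exp(-(u - c2)^2 / (2 * w2^2))
}

# One subject's raw signal: quasi-periodic beats with Gamma-distributed
# intervals, white noise, and occasional motion-artifact bumps.
synth_signal <- function(spec, cvd) {
  n <- as.integer(round(spec$fs * spec$duration))
  mean_ibi <- 60 / spec$heart_rate_mean
  cv <- 0.04
  if (cvd) cv <- cv * (1 + 0.5 * spec$morphology_shift)
  shape <- 1 / cv^2
  n_beats <- ceiling(spec$duration / mean_ibi * 1.2) + 4
  ibi <- stats::rgamma(n_beats, shape = shape, scale = mean_ibi / shape)
  onsets <- cumsum(c(0, ibi))
  sig <- numeric(n)
  t_grid <- seq_len(n) / spec$fs
  for (b in seq_len(n_beats)) {
    if (onsets[b] > spec$duration) break
    i0 <- floor(onsets[b] * spec$fs) + 1
    i1 <- min(n, ceiling((onsets[b] + ibi[b]) * spec$fs))
    if (i0 > n) break
    idx <- i0:i1
    u <- (t_grid[idx] - onsets[b]) / ibi[b]
    keep <- u >= 0 & u < 1
    sig[idx[keep]] <- sig[idx[keep]] +
      beat_template(u[keep], spec$morphology_shift, cvd)
  }
  if (spec$noise_sd > 0) sig <- sig + stats::rnorm(n, sd = spec$noise_sd)
  n_art <- stats::rpois(1, spec$artifact_rate * spec$duration / 60)
  if (n_art > 0) {
    centers <- stats::runif(n_art, 0, spec$duration)
    for (ctr in centers) {
      amp <- stats::runif(1, 1, 2.5)
      width <- stats::runif(1, 0.2, 0.6)
      sig <- sig + amp * exp(-(t_grid - ctr)^2 / (2 * width^2))
    }
  }
  sig
}

#' Generate a seeded synthetic PPG cohort
#'
#' Draws `n_cvd + n_normal` subjects according to a [cohort_spec()]. Each
#' signal is a concatenation of beats, each beat a sum of two Gaussian lobes
#' (systolic peak and dicrotic wave); beat intervals follow a Gamma
#' distribution; white noise and sparse motion-artifact bumps are added on
#' top. The same (spec, seed) pair reproduces the cohort sample-for-sample.
#'
#' @param spec A [cohort_spec()].
#' @return A list of PPG records, each a list with elements `subject_id`,
#'   `signal`, `fs` and `label` (`"CVD"` or `"NORMAL"`).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_cvd = 1, n_normal = 1,
#'                                       duration = 10, seed = 7))
#' length(cohort[[1]]$signal)  # 2000 samples
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- c(rep("CVD", spec$n_cvd), rep("NORMAL", spec$n_normal))
  with_seed(spec$seed, {
    lapply(seq_along(labels), function(i) {
      list(subject_id = sprintf("S%02d", i),
           signal = synth_signal(spec, cvd = labels[i] == "CVD"),
           fs = spec$fs,
           label = labels[i])
    })
  })
}

#' Two labeled Gaussian clouds for classifier unit tests
#'
#' Generates `2 * n_per_class` feature rows from two identity-covariance
#' Gaussian classes whose means are `separation` apart in Euclidean
#' distance. The mean-difference direction is chosen so the class
#' difference is visible to every classifier family the package
#' implements: for 24 or more columns it is a square wave along the
#' feature index (low-frequency serial structure, which
#' fluctuation-based classifiers see and per-window detrending does not
#' annihilate) with three amplified coordinates (large single-coordinate
#' offsets, which threshold-stump classifiers see); for shorter rows it
#' is a centered step. Location-based classifiers see the overall mean
#' shift in every case.
#'
#' @param n_per_class Rows per class.
#' @param dim Number of feature columns (`>= 1`).
#' @param separation Euclidean distance between class means.
#' @param seed Integer seed.
#' @return A list with `x` (matrix, `2 * n_per_class` rows) and `y`
#'   (character vector of `"CVD"` / `"NORMAL"` labels), rows shuffled.
#' @export
generate_feature_blobs <- function(n_per_class, dim, separation, seed) {
  stopifnot(n_per_class >= 1, dim >= 1, separation >= 0)
  u <- numeric(dim)
  if (dim >= 24) {
    half_period <- max(2L, as.integer(floor(dim / 12)))
    u <- rep(rep(c(1, -1), each = half_period), length.out = dim)
    boost <- pmax(1L, as.integer(round(dim * c(0.25, 0.55, 0.85))))
    u[boost] <- u[boost] * 5.5
    u <- u - mean(u)
  } else if (dim >= 2) {
    u[seq_len(floor(dim / 2))] <- 1
    u <- u - mean(u)
  } else {
    u[1] <- 1
  }
  u <- u / sqrt(sum(u^2))
  with_seed(seed, {
    n <- 2L * n_per_class
    x <- matrix(stats::rnorm(n * dim), n, dim)
    y <- rep(c("CVD", "NORMAL"), each = n_per_class)
    x[y == "CVD", ] <- x[y == "CVD", , drop = FALSE] +
      matrix(separation * u, n_per_class, dim, byrow = TRUE)
    ord <- sample.int(n)
    list(x = x[ord, , drop = FALSE], y = y[ord])
  })
}

#' Write a cohort to CSV + JSON label sidecar
#'
#' One signal column per subject (header = subject id) and a JSON object
#' mapping subject ids to class labels. [read_cohort()] inverts this.
#'
#' @param cohort List of PPG records from [generate_cohort()].
#' @param signals_path Path for the signal CSV.
#' @param labels_path Path for the JSON label sidecar.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, signals_path, labels_path) {
  stopifnot(length(cohort) >= 1)
  sig <- vapply(cohort, function(r) r$signal, numeric(length(cohort[[1]]$signal)))
  colnames(sig) <- vapply(cohort, `[[`, character(1), "subject_id")
  utils::write.csv(as.data.frame(sig), signals_path, row.names = FALSE)
  labels <- stats::setNames(
    lapply(cohort, `[[`, "label"),
    colnames(sig))
  jsonlite::write_json(labels, labels_path, auto_unbox = TRUE)
  invisible(c(signals_path, labels_path))
}
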