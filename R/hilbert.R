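#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the analytic representation `x + i H(x)` of a real signal, where
#' `H` imposes a -90 degree phase shift on positive frequencies and +90 on
#' negative ones. Computed by zeroing the negative half-spectrum and
#' doubling the positive half (DC and, for even lengths, the Nyquist bin are
#' kept as-is). The real part equals the input exactly; the magnitude
#' spectrum of `H(x)` matches that of `x` at all non-DC, non-Nyquist bins,
#' and the magnitude of the analytic signal is the instantaneous envelope.
#'
#' @param x Finite real vector, length >= 2.
#' @return Complex vector of the same length: `x + i * H(x)`.
#' @examples
#' t <- (0:199) / 200
#' a <- hilbert_transform(cos(2 * pi * 5 * t))
#' max(abs(Im(a) - sin(2 * pi * 5 * t)))  # quadrature pair, ~1e-14
#' @export
hilbert_transform <- function(x) {
  if (!is.numeric(x) || length(x) < 2 || any(!is.finite(x))) {
    stop_ppg("x must be a finite real vector of length >= 2")
  }
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  a <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  complex(real = x, imaginary = Im(a))
}

#' Reduce segments to 100 envelope features via the Hilbert transform
#'
#' For each 200-sample segment, computes the analytic-signal envelope
#' `|x + i H(x)|` (200 values) and keeps the even-indexed samples (0-based),
#' yielding exactly 100 features per segment.
#'
#' @param seg A segment matrix from [segment_record()] with 200-sample
#'   segments.
#' @return A feature matrix object (`n_segments x 100`, method `"HT"`).
#' @export
ht_reduce <- function(seg) {
  stopifnot(inherits(seg, "segment_matrix"))
  p <- ncol(seg$segments)
  if (p != 200) stop_ppg("ht_reduce expects 200-sample segments, got ", p)
  keep <- seq(1, p, by = 2)                       # 0-based even indices
  env <- t(apply(seg$segments, 1, function(s) Mod(hilbert_transform(s))))
  feature_matrix(seg$subject_id, env[, keep, drop = FALSE], seg$label, "HT",
                 list(decimation = 2L))
}
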