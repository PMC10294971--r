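# Internal helpers shared across modules.

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

# log(sum(exp(x))) without overflow
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr as-is.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed; keeps results < 2^31.
#' @keywords internal
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k) %% 2147483587)
}

#' @keywords internal
stop_ppg <- function(...) stop(..., call. = FALSE)

#' @keywords internal
check_label <- function(label) {
  if (!is.character(label) || length(label) < 1 ||
      !all(label %in% c("CVD", "NORMAL"))) {
    stop_ppg("labels must be \"CVD\" or \"NORMAL\"")
  }
  label
}

#' @keywords internal
check_finite_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_ppg(what, " must be a numeric matrix")
  }
  if (any(!is.finite(x))) stop_ppg(what, " contains non-finite values")
  x
}
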