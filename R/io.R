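#' Read a cohort from CSV signals and a JSON label sidecar
#'
#' Inverse of [write_cohort()]: the CSV holds one signal column per subject
#' (header = subject id) and the JSON sidecar maps subject ids to `"CVD"` /
#' `"NORMAL"` labels. Every subject column must have a label entry and every
#' cell must be finite; violations are hard errors naming the subject (or
#' the offending row/column).
#'
#' @param signals_path CSV of signals, one column per subject.
#' @param labels_path JSON object `{subject_id: label}`.
#' @param fs Sampling rate of the stored signals, samples/s.
#' @return A list of PPG records (see [generate_cohort()]).
#' @export
read_cohort <- function(signals_path, labels_path, fs = 200) {
  sig <- utils::read.csv(signals_path, check.names = FALSE)
  labels <- jsonlite::read_json(labels_path, simplifyVector = TRUE)
  missing <- setdiff(colnames(sig), names(labels))
  if (length(missing) > 0) {
    stop_ppg("unlabeled subject(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(!vapply(sig, is.numeric, logical(1)))
  if (length(bad) > 0) {
    stop_ppg("non-numeric signal column(s): ",
             paste(colnames(sig)[bad], collapse = ", "))
  }
  for (j in seq_along(sig)) {
    nf <- which(!is.finite(sig[[j]]))
    if (length(nf) > 0) {
      stop_ppg("non-finite value in column \"", colnames(sig)[j],
               "\", row ", nf[1])
    }
  }
  lapply(colnames(sig), function(id) {
    list(subject_id = id, signal = sig[[id]], fs = fs,
         label = check_label(as.character(labels[[id]])))
  })
}

#' Cut a PPG record into one-second segments
#'
#' Splits the signal into contiguous, non-overlapping, temporally ordered
#' rows of `fs` samples (one second each). A trailing remainder shorter than
#' one segment is dropped with a message.
#'
#' @param record A PPG record (list with `signal`, `fs`, `label`,
#'   `subject_id`).
#' @return A segment matrix object: list with `subject_id`, `segments`
#'   (matrix, `n_segments x fs`), `label`, `fs`.
#' @examples
#' rec <- list(subject_id = "S01", signal = sin(seq_len(450) / 10),
#'             fs = 200, label = "NORMAL")
#' seg <- segment_record(rec)  # 2 segments, 50 samples dropped
#' @export
segment_record <- function(record) {
  seg_len <- as.integer(round(record$fs))
  n <- length(record$signal)
  if (n < seg_len) {
    stop_ppg("signal of subject ", record$subject_id,
             " is shorter than one segment (", n, " < ", seg_len, ")")
  }
  if (any(!is.finite(record$signal))) {
    stop_ppg("signal of subject ", record$subject_id,
             " contains non-finite values")
  }
  n_seg <- n %/% seg_len
  dropped <- n - n_seg * seg_len
  if (dropped > 0) {
    message(sprintf("subject %s: dropped %d trailing samples",
                    record$subject_id, dropped))
  }
  segs <- matrix(record$signal[seq_len(n_seg * seg_len)],
                 nrow = n_seg, ncol = seg_len, byrow = TRUE)
  structure(list(subject_id = record$subject_id, segments = segs,
                 label = check_label(record$label), fs = record$fs),
            class = "segment_matrix")
}

#' @export
print.segment_matrix <- function(x, ...) {
  cat(sprintf("Segment matrix: subject %s (%s), %d segments x %d samples\n",
              x$subject_id, x$label, nrow(x$segments), ncol(x$segments)))
  invisible(x)
}

#' Remove the most artifact-like component from a segment matrix
#'
#' Treats the segment matrix as a multivariate sample (segments as
#' variables, within-segment sample index as observations), whitens it by
#' principal components, removes the component whose score series has the
#' highest sample kurtosis (heavy-tailed scores are the artifact signature),
#' and back-projects. Shape is preserved. With `enabled = FALSE` (the
#' default pipeline setting) this is the identity; on a rank-deficient
#' matrix it falls back to the identity with a warning.
#'
#' @param seg A segment matrix from [segment_record()].
#' @param enabled Apply the removal? Defaults to `TRUE` when called
#'   directly; the pipeline default keeps it off.
#' @return A segment matrix of identical shape.
#' @export
denoise_segments <- function(seg, enabled = TRUE) {
  stopifnot(inherits(seg, "segment_matrix"))
  if (!enabled) return(seg)
  x <- t(seg$segments)                       # obs = sample index, vars = segments
  if (nrow(seg$segments) < 2) stop_ppg("need at least 2 segments")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  pos <- sv$d > max(sv$d) * 1e-10
  if (sum(pos) < 2) {
    warning("rank-deficient segment matrix; denoising skipped")
    return(seg)
  }
  scores <- sv$u[, pos, drop = FALSE] %*% diag(sv$d[pos], sum(pos))
  kurt <- apply(scores, 2, function(s) {
    s <- s - mean(s)
    m2 <- mean(s^2)
    if (m2 <= 0) return(-Inf)
    mean(s^4) / m2^2 - 3
  })
  drop_k <- which.max(kurt)
  keep <- which(pos)[-drop_k]
  recon <- sv$u[, keep, drop = FALSE] %*%
    diag(sv$d[keep], length(keep)) %*% t(sv$v[, keep, drop = FALSE])
  out <- seg
  out$segments <- t(sweep(recon, 2, mu, `+`))
  out
}

#' Write / read a feature matrix as CSV with a JSON parameter sidecar
#'
#' @param fm A feature matrix object (see [ht_reduce()]).
#' @param features_path CSV path (one row per segment, 100 columns).
#' @param params_path Optional JSON path for the reduction method and its
#'   parameters.
#' @return Invisibly, the paths written.
#' @export
write_feature_csv <- function(fm, features_path, params_path = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  utils::write.csv(as.data.frame(fm$features), features_path,
                   row.names = FALSE)
  if (!is.null(params_path)) {
    jsonlite::write_json(
      list(subject_id = fm$subject_id, label = fm$label, method = fm$method,
           method_params = fm$method_params),
      params_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(features_path, params_path))
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(features_path, params_path) {
  meta <- jsonlite::read_json(params_path, simplifyVector = TRUE)
  feats <- as.matrix(utils::read.csv(features_path, check.names = FALSE))
  feature_matrix(meta$subject_id, feats, meta$label, meta$method,
                 as.list(meta$method_params))
}

# Shared constructor for reduced-feature containers.
feature_matrix <- function(subject_id, features, label, method,
                           method_params = list()) {
  check_finite_matrix(features, "feature matrix")
  structure(list(subject_id = subject_id, features = features,
                 label = check_label(label), method = method,
                 method_params = method_params),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: subject %s (%s), %d x %d, method %s\n",
              x$subject_id, x$label, nrow(x$features), ncol(x$features),
              x$method))
  invisible(x)
}
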