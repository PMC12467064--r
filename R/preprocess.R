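# Raw-EMG preprocessing: rectification, Savitzky-Golay smoothing, MVIC
# normalization, 3:1 decimation (1500 Hz -> 500 Hz).

as_signal_matrix <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("expected a numeric signal matrix (channels x samples)",
          class = "gaitphase_data_error")
  }
  x
}

#' Full-wave rectification
#'
#' @param x numeric signal matrix (channels x samples) or vector.
#' @return Elementwise absolute value, shape preserved.
#' @export
rectify <- function(x) {
  x <- as_signal_matrix(x)
  if (anyNA(x)) abort("signal contains NA", class = "gaitphase_data_error")
  abs(x)
}

#' Savitzky-Golay smoothing
#'
#' Per-channel local least-squares polynomial smoothing (default: first-order
#' polynomial over a 39-sample window). Interior samples equal the value of
#' the window's least-squares polynomial fit at the window centre; the first
#' and last half-windows come from the fits over the first and last full
#' windows evaluated at the off-centre positions.
#'
#' @param x numeric signal matrix (channels x samples) or vector.
#' @param order polynomial order.
#' @param window window length in samples (odd, greater than `order`).
#' @return Smoothed matrix, same shape as `x`.
#' @export
savgol_smooth <- function(x, order = 1L, window = 39L) {
  if (window %% 2 == 0 || window <= order) {
    abort("window must be odd and larger than the polynomial order",
          class = "gaitphase_config_error")
  }
  x <- as_signal_matrix(x)
  if (ncol(x) < window) {
    abort(sprintf("signal length %d is shorter than the smoothing window %d",
                  ncol(x), window), class = "gaitphase_data_error")
  }
  out <- t(apply(x, 1, signal::sgolayfilt, p = order, n = window))
  dimnames(out) <- dimnames(x)
  out
}

#' MVIC normalization
#'
#' Divides each channel by its maximal-voluntary-isometric-contraction
#' reference amplitude, expressing EMG as a fraction of maximal activation.
#'
#' @param x numeric signal matrix (channels x samples).
#' @param mvic per-channel positive reference values, length `nrow(x)`.
#' @return Normalized matrix.
#' @export
mvic_normalize <- function(x, mvic) {
  x <- as_signal_matrix(x)
  if (length(mvic) != nrow(x) || any(!is.finite(mvic)) || any(mvic <= 0)) {
    abort("mvic must hold one positive reference per channel",
          class = "gaitphase_config_error")
  }
  x / mvic  # column-major recycling divides row i by mvic[i]
}

#' Decimate by keeping every third sample
#'
#' Reduces 1500 Hz signals to 500 Hz by plain selection of samples
#' 1, 4, 7, ... (no anti-aliasing filter; the smoothed envelope is already
#' band-limited well below the 250 Hz Nyquist of the target rate).
#'
#' @param x numeric signal matrix (channels x samples) or vector.
#' @return Matrix with `ceiling(ncol(x) / 3)` columns.
#' @export
downsample_by_3 <- function(x) {
  x <- as_signal_matrix(x)
  if (ncol(x) < 1) abort("empty signal", class = "gaitphase_data_error")
  x[, seq(1, ncol(x), by = 3), drop = FALSE]
}

#' Preprocess a raw gait recording
#'
#' Applies, in order: rectification, Savitzky-Golay smoothing, MVIC
#' normalization and 3:1 decimation to the EMG; joint angles travel through
#' un-rectified and un-normalized and are only decimated by the same 3:1
#' selection, so EMG frames and angle frames stay aligned.
#'
#' @param rec a `gait_recording` from [simulate_subject()] or
#'   [read_recording()].
#' @param sg_order,sg_window Savitzky-Golay settings.
#' @return A `processed_recording`: list with `emg` (4 x T' non-negative
#'   normalized envelopes at 500 Hz), `hip_deg`, `knee_deg`, `fs`,
#'   `subject_id`, mapped ground truth if present, and a `provenance`
#'   character vector of the applied steps.
#' @export
preprocess_pipeline <- function(rec, sg_order = 1L, sg_window = 39L) {
  if (!inherits(rec, "gait_recording")) {
    abort("preprocess_pipeline expects a raw gait_recording",
          class = "gaitphase_data_error")
  }
  if (rec$fs <= 500) {
    abort(sprintf("recording is already at %g Hz; the pipeline consumes raw-rate data", rec$fs),
          class = "gaitphase_data_error")
  }
  emg <- rectify(rec$emg)
  emg <- savgol_smooth(emg, order = sg_order, window = sg_window)
  emg <- mvic_normalize(emg, rec$mvic)
  emg <- downsample_by_3(emg)
  hip <- drop(downsample_by_3(rec$hip_deg))
  knee <- drop(downsample_by_3(rec$knee_deg))
  out <- list(
    emg = emg, hip_deg = hip, knee_deg = knee,
    fs = rec$fs / 3, subject_id = rec$subject_id,
    provenance = c("rectify", "smooth", "normalize", "downsample")
  )
  # map ground truth (if the source is synthetic) onto the 500 Hz frame grid
  if (!is.null(rec$events)) {
    out$events <- dplyr::mutate(rec$events, sample = (.data$sample - 1L) %/% 3L + 1L)
  }
  if (!is.null(rec$labels)) {
    out$labels <- rec$labels[seq(1, length(rec$labels), by = 3)]
  }
  if (!is.null(rec$quiet_spans)) {
    qs <- rec$quiet_spans
    out$quiet_spans <- cbind(start = (qs[, "start"] - 1L) %/% 3L + 1L,
                             end = (qs[, "end"] - 1L) %/% 3L + 1L)
  }
  structure(out, class = "processed_recording")
}

#' @export
print.processed_recording <- function(x, ...) {
  cat(sprintf("<processed_recording> %s: %d frames @ %g Hz [%s]\n",
              x$subject_id, ncol(x$emg), x$fs,
              paste(x$provenance, collapse = " -> ")))
  invisible(x)
}
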