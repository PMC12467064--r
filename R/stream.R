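# Online-deployment simulation: slide a 1 s raw window over a signal buffer,
# run the full preprocessing chain plus model inference per iteration, and
# record per-window latency.

#' Streaming configuration
#'
#' Defaults mirror the online loop: a 1500-sample (1 s) raw window advanced
#' by 150 samples (0.1 s, i.e. a 10 Hz prediction update rate).
#'
#' @param window_raw window length in raw samples.
#' @param hop_raw hop between windows in raw samples.
#' @param fs_raw raw sampling rate, Hz.
#' @return A `stream_config` object.
#' @export
stream_config <- function(window_raw = 1500L, hop_raw = 150L, fs_raw = 1500) {
  if (hop_raw > window_raw) {
    abort("hop_raw must not exceed window_raw", class = "gaitphase_config_error")
  }
  structure(list(window_raw = as.integer(window_raw),
                 hop_raw = as.integer(hop_raw), fs_raw = fs_raw),
            class = "stream_config")
}

#' Number of streaming iterations over a buffer
#'
#' @param buffer_len buffer length in raw samples.
#' @param cfg a [stream_config()].
#' @return `floor((buffer_len - window_raw) / hop_raw) + 1`.
#' @export
stream_n_windows <- function(buffer_len, cfg = stream_config()) {
  if (buffer_len < cfg$window_raw) {
    abort("buffer shorter than one window", class = "gaitphase_data_error")
  }
  as.integer((buffer_len - cfg$window_raw) %/% cfg$hop_raw + 1L)
}

# one window's preprocessing: the same four steps as the batch pipeline,
# applied within the window (the smoothing never sees samples outside it)
preprocess_window <- function(w, mvic, sg_order = 1L, sg_window = 39L) {
  downsample_by_3(mvic_normalize(savgol_smooth(rectify(w), sg_order, sg_window), mvic))
}

#' Run the online streaming simulation
#'
#' Iteratively slices `cfg$window_raw` raw samples from the buffer, applies
#' rectification, Savitzky-Golay smoothing, MVIC normalization and 3:1
#' decimation, feeds the resulting 4 x 500 window to the model, and measures
#' the wall-clock time of each preprocessing + inference iteration. The
#' window then advances by `cfg$hop_raw` until the buffer is exhausted.
#'
#' @param buffer raw 4 x B signal matrix (1500 Hz).
#' @param mvic per-channel MVIC references.
#' @param model a `gait_model`, `gait_network`, or path to a checkpoint
#'   written by [save_network()] (mirroring a deployment hand-off).
#' @param cfg a [stream_config()].
#' @return List with `predictions` (2 x 500 x n_windows probability array)
#'   and `timing` (a `timing_report`: per-window tibble plus summary fields
#'   `mean_ms`, `sd_ms`, `max_ms`, `n_windows`, `memory_bytes`).
#' @export
run_stream <- function(buffer, mvic, model, cfg = stream_config()) {
  buffer <- as_signal_matrix(buffer)
  n <- stream_n_windows(ncol(buffer), cfg)
  net <- if (is.character(model)) {
    load_network(model)
  } else if (inherits(model, "gait_model")) {
    model$network
  } else {
    stopifnot(inherits(model, "gait_network"))
    model
  }
  win_500 <- cfg$window_raw %/% 3L
  preds <- array(NA_real_, dim = c(2L, win_500, n))
  ms <- numeric(n)
  for (i in seq_len(n)) {
    from <- (i - 1L) * cfg$hop_raw + 1L
    t0 <- proc.time()[["elapsed"]]
    w <- buffer[, from:(from + cfg$window_raw - 1L), drop = FALSE]
    x <- preprocess_window(w, mvic)
    preds[, , i] <- network_predict(net, x)
    ms[i] <- (proc.time()[["elapsed"]] - t0) * 1000
  }
  timing <- structure(list(
    per_window = tibble::tibble(window = seq_len(n), ms = ms),
    mean_ms = mean(ms), sd_ms = if (n > 1) sd(ms) else 0, max_ms = max(ms),
    n_windows = n, memory_bytes = memory_footprint(net$spec)
  ), class = "timing_report")
  list(predictions = preds, timing = timing)
}

#' @export
print.timing_report <- function(x, ...) {
  cat(sprintf("<timing_report> %d windows: %.2f +/- %.2f ms (max %.2f), model %.2f MB\n",
              x$n_windows, x$mean_ms, x$sd_ms, x$max_ms, x$memory_bytes / 1e6))
  invisible(x)
}

#' @export
tidy.timing_report <- function(x, ...) x$per_window

#' @export
glance.timing_report <- function(x, ...) {
  tibble::tibble(n_windows = x$n_windows, mean_ms = x$mean_ms, sd_ms = x$sd_ms,
                 max_ms = x$max_ms, memory_mb = x$memory_bytes / 1e6)
}

#' Streamed-versus-batch prediction discrepancy
#'
#' Runs the streaming loop over a recording's raw EMG and separately computes
#' each window's prediction through an explicitly composed batch path
#' (rectify, smooth, normalize, decimate on the same raw slice, then one
#' forward pass). Returns the maximum absolute probability difference —
#' a guard against silent drift between the deployment loop and the training
#' pipeline. The smoothing is windowed in both paths, so the comparison is
#' exact up to floating-point evaluation order.
#'
#' @param rec a `gait_recording`.
#' @param model model accepted by [run_stream()].
#' @param cfg a [stream_config()].
#' @return Maximum absolute prediction discrepancy.
#' @export
offline_online_equivalence <- function(rec, model, cfg = stream_config()) {
  stopifnot(inherits(rec, "gait_recording"))
  streamed <- run_stream(rec$emg, rec$mvic, model, cfg)$predictions
  net <- if (is.character(model)) load_network(model)
         else if (inherits(model, "gait_model")) model$network else model
  n <- stream_n_windows(ncol(rec$emg), cfg)
  worst <- 0
  for (i in seq_len(n)) {
    from <- (i - 1L) * cfg$hop_raw + 1L
    w <- rec$emg[, from:(from + cfg$window_raw - 1L), drop = FALSE]
    x <- downsample_by_3(mvic_normalize(savgol_smooth(rectify(w)), rec$mvic))
    p <- network_predict(net, x)
    worst <- max(worst, max(abs(p - streamed[, , i])))
  }
  worst
}
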