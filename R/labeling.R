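# Stance/swing labeling from kinematics, quiet-standing removal, the
# anticipatory label shift, and sliding-window sequence datasets.

# rolling standard deviation with truncated edge windows, O(n)
rolling_sd <- function(x, w) {
  n <- length(x)
  h <- w %/% 2
  s1 <- cumsum(c(0, x))
  s2 <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  m <- hi - lo + 1L
  sum1 <- s1[hi + 1L] - s1[lo]
  sum2 <- s2[hi + 1L] - s2[lo]
  v <- pmax((sum2 - sum1^2 / m) / pmax(m - 1L, 1L), 0)
  sqrt(v)
}

#' Detect quiet-standing spans from joint angles
#'
#' A span is flagged as quiet standing where the rolling standard deviation of
#' both the hip and knee angles stays below `thresh` over a `window_s`-second
#' window. This threshold detector replaces the hidden-Markov-model segmenter
#' used on the original recordings, whose parameters are not public; during
#' walking, joint-angle variability exceeds any sensible threshold by an order
#' of magnitude, so a rolling-variance rule separates the two regimes cleanly.
#'
#' @param proc a `processed_recording` (500 Hz).
#' @param window_s rolling-window length in seconds.
#' @param thresh angle standard-deviation threshold in degrees.
#' @return Tibble with columns `start`, `end` (1-based frame spans); zero rows
#'   if no quiet standing is present.
#' @export
detect_quiet_standing <- function(proc, window_s = 1, thresh = 0.5) {
  stopifnot(inherits(proc, "processed_recording"))
  w <- max(3L, round(window_s * proc$fs))
  quiet <- rolling_sd(proc$hip_deg, w) < thresh & rolling_sd(proc$knee_deg, w) < thresh
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 1L
  if (!any(keep)) return(tibble::tibble(start = integer(0), end = integer(0)))
  h <- w %/% 2
  n <- length(quiet)
  spans <- tibble::tibble(start = pmax(starts[keep] - h, 1L),
                          end = pmin(ends[keep] + h, n))
  # merge spans that touch after expansion
  merged <- spans[1, ]
  for (i in seq_len(nrow(spans))[-1]) {
    if (spans$start[i] <= merged$end[nrow(merged)] + 1L) {
      merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], spans$end[i])
    } else {
      merged <- dplyr::bind_rows(merged, spans[i, ])
    }
  }
  merged
}

#' Detect heel-strike and toe-off events from the knee angle
#'
#' Threshold detector with hysteresis: a toe-off is emitted at each upward
#' crossing of the knee angle through `theta_swing_on`, a heel-strike at each
#' downward crossing through `theta_stance_on`. The two thresholds straddle
#' the knee's fast stance/swing transitions, and the hysteresis pair enforces
#' strict HS/TO alternation. The knee angle is lightly smoothed
#' (Savitzky-Golay, order 3, 21 frames) before thresholding to suppress
#' sensor noise. Quiet-standing spans must have been removed first.
#'
#' @param proc a `processed_recording` (500 Hz) free of quiet standing.
#' @param theta_swing_on upward (toe-off) threshold, degrees.
#' @param theta_stance_on downward (heel-strike) threshold, degrees; must be
#'   below `theta_swing_on`.
#' @return An event timeline: tibble with `sample` (1-based frame) and `type`
#'   ("HS" or "TO"), strictly increasing and alternating.
#' @export
detect_gait_events <- function(proc, theta_swing_on = 30, theta_stance_on = 15) {
  stopifnot(inherits(proc, "processed_recording"))
  if (theta_swing_on <= theta_stance_on) {
    abort("hysteresis requires theta_swing_on > theta_stance_on",
          class = "gaitphase_config_error")
  }
  ka <- proc$knee_deg
  if (length(ka) >= 21) ka <- drop(savgol_smooth(ka, order = 3L, window = 21L))
  ev <- hysteresis_crossings(ka, up = theta_swing_on, down = theta_stance_on)
  if (nrow(ev) < 2) {
    abort("fewer than one full gait cycle detected", class = "gaitphase_data_error")
  }
  ev
}

validate_timeline <- function(timeline) {
  if (!is.data.frame(timeline) || nrow(timeline) == 0) {
    abort("empty event timeline", class = "gaitphase_data_error")
  }
  if (is.unsorted(timeline$sample, strictly = TRUE)) {
    abort("event samples must be strictly increasing", class = "gaitphase_data_error")
  }
  if (nrow(timeline) > 1 &&
      any(timeline$type[-1] == timeline$type[-nrow(timeline)])) {
    abort("heel-strikes and toe-offs must alternate", class = "gaitphase_data_error")
  }
  invisible(timeline)
}

#' Frame labels from an event timeline
#'
#' Frames from a heel-strike up to (excluding) the next toe-off are stance;
#' frames from a toe-off up to the next heel-strike are swing. Frames before
#' the first event take the class consistent with that event's type.
#'
#' @param timeline tibble of alternating `sample`/`type` events.
#' @param n_frames track length.
#' @return A `label_track`: list with integer `labels` (1 = stance,
#'   2 = swing), `shift_frames = 0` and `fs = 500`.
#' @export
events_to_labels <- function(timeline, n_frames) {
  validate_timeline(timeline)
  structure(list(labels = events_to_label_vector(timeline, n_frames),
                 shift_frames = 0L, fs = 500),
            class = "label_track")
}

#' @export
print.label_track <- function(x, ...) {
  cat(sprintf("<label_track> %d frames, shift %d, %.1f%% stance\n",
              length(x$labels), x$shift_frames, 100 * mean(x$labels == STANCE)))
  invisible(x)
}

#' Advance labels to exploit anticipatory muscle activation
#'
#' Muscle activation precedes the kinematic events it produces by roughly
#' 100-200 ms, so advancing the label array teaches the network to announce
#' the upcoming phase transition. `out[t] = in[t + shift_frames]`; the final
#' `shift_frames` frames have no future label and are dropped (the paired
#' signal must be truncated to the track length before windowing — padding
#' would fabricate labels).
#'
#' @param track a `label_track`.
#' @param shift_frames advance in frames at 500 Hz (120 ms = 60 frames).
#' @return A shorter `label_track` with `shift_frames` recorded.
#' @export
shift_labels <- function(track, shift_frames = 60L) {
  stopifnot(inherits(track, "label_track"), shift_frames >= 0)
  n <- length(track$labels)
  if (shift_frames >= n) {
    abort("shift is not smaller than the track length", class = "gaitphase_data_error")
  }
  if (shift_frames == 0) return(track)
  track$labels <- track$labels[(shift_frames + 1L):n]
  track$shift_frames <- track$shift_frames + as.integer(shift_frames)
  track
}

onehot_labels <- function(labels, win_starts, win) {
  n <- length(win_starts)
  y <- array(0, dim = c(n, 2L, win))
  for (i in seq_len(n)) {
    lab <- labels[win_starts[i]:(win_starts[i] + win - 1L)]
    y[i, 1L, ] <- as.numeric(lab == STANCE)
    y[i, 2L, ] <- as.numeric(lab == SWING)
  }
  y
}

#' Window a processed recording into model-ready sequences
#'
#' Slides a `win`-frame window (default 1 s at 500 Hz) in steps of `step`
#' frames (default 90% overlap, i.e. a 10 Hz update rate) over the recording,
#' pairing each 4 x 500 EMG window with a one-hot 2 x 500 label array (class
#' order: stance, swing). The signal is truncated to the label-track length,
#' so shifted tracks automatically drop the unlabeled tail.
#'
#' @param proc a `processed_recording`.
#' @param track a `label_track` for the same recording.
#' @param win window length in frames.
#' @param step hop between consecutive windows in frames.
#' @param labeling_mode "kinematics" or "shifted" tag kept in the manifest.
#' @return A `sequence_dataset`: list with `x` (N x 4 x win), `y`
#'   (N x 2 x win one-hot), `subject_ids`, `window_start`, `labeling_mode`.
#' @export
make_sequences <- function(proc, track, win = 500L, step = 50L,
                           labeling_mode = if (track$shift_frames > 0) "shifted" else "kinematics") {
  stopifnot(inherits(proc, "processed_recording"), inherits(track, "label_track"))
  n <- min(length(track$labels), ncol(proc$emg))
  if (n < win) {
    abort(sprintf("track length %d is shorter than the window %d", n, win),
          class = "gaitphase_data_error")
  }
  starts <- seq(1L, n - win + 1L, by = step)
  N <- length(starts)
  x <- array(0, dim = c(N, nrow(proc$emg), win))
  for (i in seq_len(N)) {
    x[i, , ] <- proc$emg[, starts[i]:(starts[i] + win - 1L)]
  }
  structure(list(
    x = x,
    y = onehot_labels(track$labels, starts, win),
    subject_ids = rep(proc$subject_id, N),
    window_start = starts,
    labeling_mode = labeling_mode
  ), class = "sequence_dataset")
}

#' @export
print.sequence_dataset <- function(x, ...) {
  cat(sprintf("<sequence_dataset> %d windows of %d x %d, %d subjects, %s labeling\n",
              dim(x$x)[1], dim(x$x)[2], dim(x$x)[3],
              length(unique(x$subject_ids)), x$labeling_mode))
  invisible(x)
}

#' Combine sequence datasets
#'
#' @param datasets list of `sequence_dataset` objects with equal window shape
#'   and labeling mode.
#' @return A single `sequence_dataset`.
#' @export
bind_datasets <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  if (length(datasets) == 1) return(datasets[[1]])
  d1 <- dim(datasets[[1]]$x)[-1]
  modes <- unique(vapply(datasets, function(d) d$labeling_mode, character(1)))
  if (length(modes) > 1) {
    abort("cannot bind datasets with different labeling modes",
          class = "gaitphase_config_error")
  }
  ns <- vapply(datasets, function(d) dim(d$x)[1], numeric(1))
  N <- sum(ns)
  x <- array(0, dim = c(N, d1))
  y <- array(0, dim = c(N, 2L, d1[2]))
  at <- 0L
  for (d in datasets) {
    idx <- at + seq_len(dim(d$x)[1])
    x[idx, , ] <- d$x
    y[idx, , ] <- d$y
    at <- at + dim(d$x)[1]
  }
  structure(list(
    x = x, y = y,
    subject_ids = unlist(lapply(datasets, function(d) d$subject_ids)),
    window_start = unlist(lapply(datasets, function(d) d$window_start)),
    labeling_mode = modes
  ), class = "sequence_dataset")
}

#' Subset a sequence dataset by window index
#'
#' @param ds a `sequence_dataset`.
#' @param idx integer window indices.
#' @return The subset `sequence_dataset`.
#' @export
subset_dataset <- function(ds, idx) {
  stopifnot(inherits(ds, "sequence_dataset"))
  structure(list(
    x = ds$x[idx, , , drop = FALSE],
    y = ds$y[idx, , , drop = FALSE],
    subject_ids = ds$subject_ids[idx],
    window_start = ds$window_start[idx],
    labeling_mode = ds$labeling_mode
  ), class = "sequence_dataset")
}

# split a processed recording into its active (non-quiet) segments
split_active_segments <- function(proc, spans) {
  n <- ncol(proc$emg)
  if (is.null(spans) || nrow(spans) == 0) return(list(proc))
  keep_runs <- list()
  cur <- 1L
  for (i in seq_len(nrow(spans))) {
    if (spans$start[i] > cur) keep_runs <- c(keep_runs, list(c(cur, spans$start[i] - 1L)))
    cur <- max(cur, spans$end[i] + 1L)
  }
  if (cur <= n) keep_runs <- c(keep_runs, list(c(cur, n)))
  lapply(keep_runs, function(r) {
    idx <- r[1]:r[2]
    seg <- proc
    seg$emg <- proc$emg[, idx, drop = FALSE]
    seg$hip_deg <- proc$hip_deg[idx]
    seg$knee_deg <- proc$knee_deg[idx]
    seg$labels <- proc$labels[idx]
    seg$events <- NULL
    seg$quiet_spans <- NULL
    seg
  })
}

#' Full labeling pipeline: raw recordings to a windowed dataset
#'
#' For each recording: preprocess to 500 Hz, detect and remove quiet-standing
#' spans, detect heel-strike/toe-off events per active segment, derive frame
#' labels, optionally advance them by `shift_frames`, and window each segment
#' independently (windows never span a removed quiet bout). Segments from all
#' recordings are concatenated into one dataset.
#'
#' @param recordings list of `gait_recording` objects.
#' @param shift_frames label advance in frames (0 for kinematics labeling,
#'   60 for the 120 ms anticipatory shift).
#' @param win,step window length and hop in frames.
#' @param quiet_window_s,quiet_thresh quiet-standing detector settings.
#' @return A `sequence_dataset` pooling all recordings.
#' @export
prepare_dataset <- function(recordings, shift_frames = 0L, win = 500L, step = 50L,
                            quiet_window_s = 1, quiet_thresh = 0.5) {
  stopifnot(length(recordings) >= 1)
  mode <- if (shift_frames > 0) "shifted" else "kinematics"
  parts <- list()
  for (rec in recordings) {
    proc <- preprocess_pipeline(rec)
    spans <- detect_quiet_standing(proc, window_s = quiet_window_s,
                                   thresh = quiet_thresh)
    for (seg in split_active_segments(proc, spans)) {
      if (ncol(seg$emg) < win + shift_frames + 1L) next
      ev <- detect_gait_events(seg)
      track <- events_to_labels(ev, ncol(seg$emg))
      if (shift_frames > 0) track <- shift_labels(track, shift_frames)
      parts <- c(parts, list(make_sequences(seg, track, win = win, step = step,
                                            labeling_mode = mode)))
    }
  }
  if (!length(parts)) {
    abort("no segment was long enough to window", class = "gaitphase_data_error")
  }
  bind_datasets(parts)
}

#' Manifest of a sequence dataset
#'
#' @param ds a `sequence_dataset`.
#' @return Tibble with one row per window: `subject_id`, `window_start`,
#'   `labeling_mode`.
#' @export
dataset_manifest <- function(ds) {
  stopifnot(inherits(ds, "sequence_dataset"))
  tibble::tibble(subject_id = ds$subject_ids,
                 window_start = ds$window_start,
                 labeling_mode = ds$labeling_mode)
}
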