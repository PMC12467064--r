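# Synthetic exoskeleton-gait generator: cyclic stance/swing kinematics,
# anticipatory muscle-activation envelopes, EMG as envelope-modulated
# broadband noise, quiet-standing insertions.

CHANNELS <- c("BF", "TA", "VL", "SOL")
STANCE <- 1L
SWING <- 2L
CLASS_LEVELS <- c("stance", "swing")

# knee-angle hysteresis thresholds (degrees); shared by the generator's
# ground-truth event definition and by detect_gait_events() defaults
KA_SWING_ON <- 30
KA_STANCE_ON <- 15

# cubic smoothstep on [0, 1]
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# value of u at which smoothstep(u) equals s
smoothstep_inv <- function(s) {
  stats::uniroot(function(u) u * u * (3 - 2 * u) - s, c(0, 1), tol = 1e-12)$root
}

#' Configuration for the synthetic gait generator
#'
#' Defaults emulate slow exoskeleton-assisted walking (about 1.3 km/h, some
#' 35 strides per minute), with muscle activation leading kinematic events by
#' 120 ms — the anticipatory lead the labeling strategy exploits.
#'
#' @param fs_raw raw sampling rate in Hz.
#' @param cadence strides per minute.
#' @param stance_fraction fraction of the gait cycle spent in stance.
#' @param lead_ms anticipatory lead of muscle-activation onsets over the
#'   kinematic events they precede, in milliseconds.
#' @param n_strides number of strides to simulate.
#' @param quiet_bouts list of `c(start_s, duration_s)` quiet-standing bouts
#'   inserted into the recording at the given times.
#' @param mvic four per-muscle maximal-voluntary-contraction reference
#'   amplitudes (BF, TA, VL, SOL), arbitrary units.
#' @param noise_sd standard deviation of the broadband EMG carrier noise.
#' @param baseline_sd additive sensor-noise scale, relative to each muscle's
#'   MVIC.
#' @param angle_noise_sd additive joint-angle sensor noise, degrees.
#' @param gain per-muscle multiplicative gain (subject heterogeneity); the
#'   recorded MVIC references do not include it, so it survives normalization.
#' @param seed integer RNG seed.
#' @return A `gait_sim_config` object.
#' @export
gait_sim_config <- function(fs_raw = 1500, cadence = 35, stance_fraction = 0.60,
                            lead_ms = 120, n_strides = 20,
                            quiet_bouts = list(),
                            mvic = c(BF = 0.9, TA = 1.1, VL = 1.0, SOL = 0.8),
                            noise_sd = 1, baseline_sd = 0.02,
                            angle_noise_sd = 0.05, gain = c(1, 1, 1, 1),
                            seed = 1L) {
  if (fs_raw <= 0 || n_strides <= 0) {
    abort("fs_raw and n_strides must be positive", class = "gaitphase_config_error")
  }
  if (stance_fraction <= 0 || stance_fraction >= 1) {
    abort("stance_fraction must lie in (0, 1)", class = "gaitphase_config_error")
  }
  if (lead_ms < 0) abort("lead_ms must be >= 0", class = "gaitphase_config_error")
  if (length(mvic) != 4 || any(mvic <= 0)) {
    abort("mvic must hold 4 positive per-muscle references", class = "gaitphase_config_error")
  }
  names(mvic) <- CHANNELS
  structure(list(fs_raw = fs_raw, cadence = cadence,
                 stance_fraction = stance_fraction, lead_ms = lead_ms,
                 n_strides = as.integer(n_strides), quiet_bouts = quiet_bouts,
                 mvic = mvic, noise_sd = noise_sd, baseline_sd = baseline_sd,
                 angle_noise_sd = angle_noise_sd, gain = gain,
                 seed = as.integer(seed)),
            class = "gait_sim_config")
}

# Muscle envelope timing (package defaults). Each muscle has one activation
# bump per cycle, a raised cosine whose onset occurs lead_ms before the
# kinematic event it precedes: BF (terminal swing / loading response), TA
# (around heel-strike) and VL (loading into mid-stance) precede heel-strike;
# SOL (late-stance push-off) precedes toe-off. Widths in cycle fractions.
muscle_timing <- function(stance_fraction) {
  tibble::tibble(
    muscle = CHANNELS,
    event = c("HS", "HS", "HS", "TO"),
    event_phase = c(1, 1, 1, stance_fraction),
    width = c(0.30, 0.35, 0.40, 0.30)
  )
}

# knee trajectory over unwrapped phase ph (strides); transitions are fast
# (~3% of a cycle) and placed so that the 30-degree upward crossing falls at
# the nominal toe-off phase and the 15-degree downward crossing at the
# heel-strike phase, making threshold-derived events coincide with the
# configured stance fraction
knee_curve <- function(ph, n_strides, stance_fraction, rise_w = 0.03, fall_w = 0.03) {
  base <- 5
  swing_amp <- 50
  load_amp <- 6
  phi <- ph - floor(ph)
  # loading-response flexion early in stance (stays below the 15-degree
  # hysteresis threshold)
  load <- load_amp * 0.5 * (1 - cos(2 * pi * pmin(pmax((phi - 0.03) / 0.18, 0), 1)))
  ka <- base + load
  # rise centered so smoothstep = 0.5 (knee = 30 deg) exactly at stance_fraction;
  # fall placed so smoothstep = 0.2 (knee = 15 deg) exactly at the cycle end
  u_hs <- smoothstep_inv((KA_STANCE_ON - base) / swing_amp)
  for (k in seq_len(n_strides) - 1) {
    t0 <- k + stance_fraction - rise_w / 2
    t1 <- k + 1 + u_hs * fall_w
    idx <- which(ph >= t0 & ph <= t1 + fall_w)
    if (!length(idx)) next
    rise <- smoothstep((ph[idx] - t0) / rise_w)
    fall <- smoothstep((t1 - ph[idx]) / fall_w)
    ka[idx] <- ka[idx] + swing_amp * rise * fall - load[idx] * rise * fall
  }
  ka
}

# alternating hysteresis event detector: toe-off at upward crossings of `up`,
# heel-strike at downward crossings of `down`
hysteresis_crossings <- function(ka, up = KA_SWING_ON, down = KA_STANCE_ON) {
  above <- ka > up
  below <- ka < down
  state <- if (ka[1] >= up) SWING else STANCE
  ev_idx <- integer(0)
  ev_type <- character(0)
  t <- 2L
  n <- length(ka)
  while (t <= n) {
    if (state == STANCE) {
      nxt <- which(above[t:n])
      if (!length(nxt)) break
      t <- t + nxt[1] - 1L
      ev_idx <- c(ev_idx, t); ev_type <- c(ev_type, "TO"); state <- SWING
    } else {
      nxt <- which(below[t:n])
      if (!length(nxt)) break
      t <- t + nxt[1] - 1L
      ev_idx <- c(ev_idx, t); ev_type <- c(ev_type, "HS"); state <- STANCE
    }
    t <- t + 1L
  }
  tibble::tibble(sample = ev_idx, type = ev_type)
}

# frame labels from an alternating event table; frames before the first event
# take the class consistent with that event's type
events_to_label_vector <- function(events, n_frames) {
  if (nrow(events) == 0) {
    abort("cannot label a recording without gait events", class = "gaitphase_data_error")
  }
  labels <- integer(n_frames)
  first <- events$type[1]
  labels[seq_len(min(events$sample[1] - 1L, n_frames))] <-
    if (first == "HS") SWING else STANCE
  for (i in seq_len(nrow(events))) {
    from <- events$sample[i]
    to <- if (i < nrow(events)) events$sample[i + 1L] - 1L else n_frames
    if (from > n_frames) break
    labels[from:min(to, n_frames)] <- if (events$type[i] == "HS") STANCE else SWING
  }
  labels
}

#' Simulate one subject's gait recording
#'
#' Generates raw 4-channel EMG at `fs_raw` together with hip and knee flexion
#' angles and full ground truth: heel-strike/toe-off event indices, per-frame
#' stance/swing labels, and the per-muscle activation envelopes. The knee
#' peaks at about 55 degrees in mid-swing and is nearly extended at
#' heel-strike; the hip oscillates between about +25 degrees (heel-strike)
#' and -20 degrees (late stance). Each muscle's activation envelope is a
#' raised-cosine bump whose onset precedes its kinematic event by
#' `cfg$lead_ms`; the EMG is that envelope multiplying zero-mean broadband
#' noise at MVIC scale, plus additive baseline noise. Output is deterministic
#' given `cfg$seed`.
#'
#' @param cfg a [gait_sim_config()].
#' @param subject_id subject identifier string.
#' @return A `gait_recording`: list with elements `subject_id`, `fs`,
#'   `emg` (4 x T matrix, rows BF/TA/VL/SOL), `hip_deg`, `knee_deg`,
#'   `events` (tibble of 1-based `sample` indices and `type` in HS/TO),
#'   `labels` (integer per frame, 1 = stance, 2 = swing), `envelopes`
#'   (4 x T), `mvic`, and the generating `config`.
#' @export
simulate_subject <- function(cfg, subject_id = "S01") {
  stopifnot(inherits(cfg, "gait_sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)

  fs <- cfg$fs_raw
  stride_s <- 60 / cfg$cadence
  n_frames <- round(cfg$n_strides * stride_s * fs)
  t_idx <- seq_len(n_frames) - 1L
  ph <- t_idx / (stride_s * fs)          # unwrapped phase in strides
  phi <- ph - floor(ph)

  knee <- knee_curve(ph, cfg$n_strides, cfg$stance_fraction)
  hip <- 2.5 + 22.5 * cos(2 * pi * phi)

  events <- hysteresis_crossings(knee)
  labels <- events_to_label_vector(events, n_frames)

  # envelopes: onset exactly lead_ms before the associated event phase
  lead_ph <- (cfg$lead_ms / 1000) / stride_s
  timing <- muscle_timing(cfg$stance_fraction)
  env <- matrix(0, nrow = 4, ncol = n_frames, dimnames = list(CHANNELS, NULL))
  for (m in seq_len(4)) {
    onset_ph <- timing$event_phase[m] - lead_ph
    w <- timing$width[m]
    for (k in (seq_len(cfg$n_strides + 1L) - 2L)) {  # strides -1 .. n-1 cover edges
      t0 <- k + onset_ph
      idx <- which(ph >= t0 & ph <= t0 + w)
      if (!length(idx)) next
      env[m, idx] <- env[m, idx] +
        0.5 * (1 - cos(2 * pi * (ph[idx] - t0) / w))
    }
  }

  emg <- matrix(0, nrow = 4, ncol = n_frames, dimnames = list(CHANNELS, NULL))
  for (m in seq_len(4)) {
    carrier <- rnorm(n_frames, 0, cfg$noise_sd)
    emg[m, ] <- env[m, ] * carrier * cfg$mvic[m] * cfg$gain[m] +
      rnorm(n_frames, 0, cfg$baseline_sd * cfg$mvic[m])
  }

  if (cfg$angle_noise_sd > 0) {
    knee <- knee + rnorm(n_frames, 0, cfg$angle_noise_sd)
    hip <- hip + rnorm(n_frames, 0, cfg$angle_noise_sd)
  }

  rec <- list(subject_id = subject_id, fs = fs, emg = emg, hip_deg = hip,
              knee_deg = knee, events = events, labels = labels,
              envelopes = env, mvic = cfg$mvic, config = cfg)
  class(rec) <- "gait_recording"

  for (qb in cfg$quiet_bouts) {
    rec <- insert_quiet_bout(rec, start_s = qb[1], duration_s = qb[2], cfg = cfg)
  }
  rec
}

# splice a quiet-standing segment into a recording at start_s, pushing
# subsequent samples and events later
insert_quiet_bout <- function(rec, start_s, duration_s, cfg) {
  fs <- rec$fs
  at <- max(1L, min(round(start_s * fs) + 1L, ncol(rec$emg) + 1L))
  len <- round(duration_s * fs)
  quiet_knee <- 5 + rnorm(len, 0, cfg$angle_noise_sd)
  quiet_hip <- rnorm(len, 0, cfg$angle_noise_sd)
  quiet_emg <- matrix(rnorm(4 * len, 0, cfg$baseline_sd) * rep(cfg$mvic, len),
                      nrow = 4, dimnames = list(CHANNELS, NULL))
  splice_mat <- function(m, q) cbind(m[, seq_len(at - 1L), drop = FALSE], q,
                                     m[, seq(at, ncol(m)), drop = FALSE][, seq_len(ncol(m) - at + 1L), drop = FALSE])
  splice_vec <- function(v, q) c(v[seq_len(at - 1L)], q, v[seq(at, length(v))][seq_len(length(v) - at + 1L)])
  n <- ncol(rec$emg)
  keep_tail <- at <= n
  rec$emg <- if (keep_tail) splice_mat(rec$emg, quiet_emg) else cbind(rec$emg, quiet_emg)
  rec$envelopes <- if (keep_tail) splice_mat(rec$envelopes, matrix(0, 4, len)) else cbind(rec$envelopes, matrix(0, 4, len))
  rec$knee_deg <- if (keep_tail) splice_vec(rec$knee_deg, quiet_knee) else c(rec$knee_deg, quiet_knee)
  rec$hip_deg <- if (keep_tail) splice_vec(rec$hip_deg, quiet_hip) else c(rec$hip_deg, quiet_hip)
  lab_at <- rec$labels[max(1L, min(at, length(rec$labels)))]
  rec$labels <- if (keep_tail) splice_vec(rec$labels, rep(lab_at, len)) else c(rec$labels, rep(lab_at, len))
  rec$events$sample <- ifelse(rec$events$sample >= at, rec$events$sample + len,
                              rec$events$sample)
  rec$quiet_spans <- rbind(rec$quiet_spans, c(start = at, end = at + len - 1L))
  rec
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> %s: %d frames @ %g Hz, %d events, %d quiet bouts\n",
              x$subject_id, ncol(x$emg), x$fs, nrow(x$events),
              if (is.null(x$quiet_spans)) 0L else nrow(x$quiet_spans)))
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds, cadence jitter (uniform within ±10%) and per-muscle
#' lognormal gain jitter (sd 0.2 on the log scale) are all derived
#' deterministically from `master_seed`, so subjects are distinguishable and
#' the cohort is reproducible. The gain jitter is not reflected in the
#' recorded MVIC references, so between-subject amplitude differences survive
#' MVIC normalization (as they do across real subjects).
#'
#' @param cfg a [gait_sim_config()] used as the cohort template.
#' @param n_subjects number of subjects (>= 1).
#' @param master_seed integer seed for the whole cohort.
#' @return List of `gait_recording` objects with subject ids "S01", "S02", ...
#' @export
simulate_cohort <- function(cfg, n_subjects, master_seed = 1L) {
  stopifnot(inherits(cfg, "gait_sim_config"))
  if (n_subjects < 1) {
    abort("n_subjects must be >= 1", class = "gaitphase_config_error")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(master_seed))
  cad_jit <- runif(n_subjects, 0.9, 1.1)
  gain_jit <- matrix(exp(rnorm(4 * n_subjects, 0, 0.2)), nrow = 4)
  seeds <- sample.int(.Machine$integer.max, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    cfg_i <- cfg
    cfg_i$cadence <- cfg$cadence * cad_jit[i]
    cfg_i$gain <- gain_jit[, i]
    cfg_i$seed <- seeds[i]
    simulate_subject(cfg_i, subject_id = sprintf("S%02d", i))
  })
}
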