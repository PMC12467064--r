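test_that("simulation is deterministic and validates its configuration", {
  cfg <- gait_sim_config(n_strides = 4, seed = 9)
  r1 <- simulate_subject(cfg, "S01")
  r2 <- simulate_subject(cfg, "S01")
  expect_identical(r1$emg, r2$emg)
  expect_identical(r1$events, r2$events)

  expect_error(gait_sim_config(n_strides = 0), class = "gaitphase_config_error")
  expect_error(gait_sim_config(fs_raw = -1), class = "gaitphase_config_error")
  expect_error(gait_sim_config(stance_fraction = 1.2), class = "gaitphase_config_error")
  expect_error(gait_sim_config(mvic = c(1, -1, 1, 1)), class = "gaitphase_config_error")
})

test_that("ground-truth events alternate and labels change exactly at events", {
  rec <- fix_recording()
  ev <- rec$events
  expect_true(all(diff(ev$sample) > 0))
  expect_true(all(ev$type[-1] != ev$type[-nrow(ev)]))
  # labels flip exactly at event samples
  change_at <- which(diff(rec$labels) != 0) + 1L
  expect_identical(change_at, ev$sample[ev$sample > 1])
  for (i in seq_len(nrow(ev))) {
    expected <- if (ev$type[i] == "HS") 1L else 2L
    expect_identical(rec$labels[ev$sample[i]], expected)
  }
})

test_that("stance fraction of the generated labels matches the configuration", {
  rec <- simulate_subject(gait_sim_config(n_strides = 50, seed = 3), "S01")
  # measure between the first and last event so edge partial phases drop out
  ev <- rec$events
  span <- ev$sample[1]:(ev$sample[nrow(ev)] - 1L)
  expect_equal(mean(rec$labels[span] == 1L), 0.60, tolerance = 0.02 / 0.60)
})

test_that("knee and hip trajectories satisfy the label/angle consistency rules", {
  rec <- fix_recording()  # noise-free angles
  hs <- rec$events$sample[rec$events$type == "HS"]
  to <- rec$events$sample[rec$events$type == "TO"]
  expect_true(all(rec$knee_deg[hs] < 15))
  # mid-swing = midpoint between each toe-off and the following heel-strike
  mid <- vapply(to, function(t) {
    nxt <- hs[hs > t]
    if (length(nxt)) round((t + nxt[1]) / 2) else NA_integer_
  }, numeric(1))
  mid <- mid[!is.na(mid)]
  expect_true(all(rec$knee_deg[mid] >= 50 & rec$knee_deg[mid] <= 60))
  # hip oscillates between roughly +25 (heel-strike) and -20 (late stance)
  expect_true(all(abs(rec$hip_deg[hs] - 25) < 2))
  expect_lt(min(rec$hip_deg), -18)
})

test_that("every muscle envelope onset leads its kinematic event by lead_ms", {
  rec <- fix_recording()
  fs <- rec$fs
  lead_frames <- round(120 / 1000 * fs)
  hs <- rec$events$sample[rec$events$type == "HS"]
  to <- rec$events$sample[rec$events$type == "TO"]
  onsets <- function(v) which(v[-1] > 0 & v[-length(v)] == 0) + 1L
  for (m in c("BF", "TA", "VL")) {
    d <- vapply(onsets(rec$envelopes[m, ]), function(o) {
      nxt <- hs[hs >= o]
      if (length(nxt)) nxt[1] - o else NA_real_
    }, numeric(1))
    expect_true(all(abs(d[!is.na(d)] - lead_frames) <= 1))
  }
  d_sol <- vapply(onsets(rec$envelopes["SOL", ]), function(o) {
    nxt <- to[to >= o]
    if (length(nxt)) nxt[1] - o else NA_real_
  }, numeric(1))
  expect_true(all(abs(d_sol[!is.na(d_sol)] - lead_frames) <= 1))
})

test_that("cross-correlation of the TA onset train with the heel-strike train peaks at -120 ms", {
  rec <- fix_recording()
  n <- ncol(rec$emg)
  on_ind <- rep(0, n)
  on_ind[which(rec$envelopes["TA", -1] > 0 & rec$envelopes["TA", -n] == 0) + 1L] <- 1
  hs_ind <- rep(0, n)
  hs_ind[rec$events$sample[rec$events$type == "HS"]] <- 1
  lags <- -400:0
  cc <- vapply(lags, function(L) {
    # correlation of onset train with the HS train shifted by L frames
    t <- seq_len(n)
    tt <- t - L
    ok <- tt >= 1 & tt <= n
    sum(on_ind[t[ok]] * hs_ind[tt[ok]])
  }, numeric(1))
  best_lag <- lags[which.max(cc)]
  expect_lte(abs(best_lag - (-round(0.120 * rec$fs))), 1)
})

test_that("EMG-derived TA onsets lead heel-strike by about 120 ms", {
  # onsets estimated from the rectified-smoothed EMG channel itself; the
  # raised-cosine envelope rises slowly from zero, so threshold crossings are
  # biased by a few milliseconds and the check uses a 15 ms tolerance
  rec <- simulate_subject(gait_sim_config(n_strides = 12, baseline_sd = 0,
                                          angle_noise_sd = 0, seed = 5), "S01")
  sm <- drop(savgol_smooth(rectify(rec$emg["TA", , drop = FALSE])))
  thr <- 1e-3 * max(sm)
  up <- which(sm[-1] > thr & sm[-length(sm)] <= thr) + 1L
  up <- up[c(TRUE, diff(up) > 1000)]  # one onset per cycle
  hs <- rec$events$sample[rec$events$type == "HS"]
  d <- vapply(up, function(o) {
    nxt <- hs[hs >= o]
    if (length(nxt)) nxt[1] - o else NA_real_
  }, numeric(1))
  d <- d[!is.na(d)]
  expect_true(all(abs(d - 180) <= 0.015 * rec$fs))
})

test_that("cohorts are reproducible, distinguishable, and invariant-clean", {
  cfg <- gait_sim_config(n_strides = 3, seed = 1)
  c1 <- simulate_cohort(cfg, 3, master_seed = 11)
  c2 <- simulate_cohort(cfg, 3, master_seed = 11)
  expect_identical(lapply(c1, `[[`, "emg"), lapply(c2, `[[`, "emg"))
  expect_identical(vapply(c1, `[[`, character(1), "subject_id"),
                   c("S01", "S02", "S03"))
  # subjects differ (gain/cadence jitter)
  expect_false(identical(ncol(c1[[1]]$emg), ncol(c1[[2]]$emg)) &&
               identical(c1[[1]]$emg[, 1:100], c1[[2]]$emg[, 1:100]))
  expect_error(simulate_cohort(cfg, 0), class = "gaitphase_config_error")
  # invariant sweep over a larger cohort
  for (rec in simulate_cohort(gait_sim_config(n_strides = 2, seed = 1), 26,
                              master_seed = 2)) {
    T <- ncol(rec$emg)
    expect_identical(length(rec$hip_deg), T)
    expect_identical(length(rec$knee_deg), T)
    expect_identical(length(rec$labels), T)
    expect_true(all(rec$events$type[-1] != rec$events$type[-nrow(rec$events)]))
  }
})

test_that("recordings render to a faceted signal plot", {
  expect_s3_class(autoplot(fix_recording(), seconds = 4), "ggplot")
})

test_that("quiet bouts silence the envelopes and displace later events", {
  cfg <- gait_sim_config(n_strides = 8, quiet_bouts = list(c(4, 3)), seed = 6)
  rec <- simulate_subject(cfg, "S01")
  span <- rec$quiet_spans[1, ]
  idx <- span["start"]:span["end"]
  expect_true(all(rec$envelopes[, idx] == 0))
  expect_lt(sd(rec$knee_deg[idx]), 0.2)
  # no events inside the bout, alternation preserved
  expect_false(any(rec$events$sample %in% idx))
  expect_true(all(rec$events$type[-1] != rec$events$type[-nrow(rec$events)]))
  # total length grew by the bout
  base <- simulate_subject(gait_sim_config(n_strides = 8, seed = 6), "S01")
  expect_identical(ncol(rec$emg), as.integer(ncol(base$emg) + round(3 * cfg$fs_raw)))
})
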