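test_that("quiet-standing detection recovers inserted bouts", {
  proc <- fix_processed()
  expect_identical(nrow(detect_quiet_standing(proc)), 0L)

  recq <- simulate_subject(gait_sim_config(n_strides = 10,
                                           quiet_bouts = list(c(5, 5)),
                                           seed = 3), "S02")
  pq <- preprocess_pipeline(recq)
  spans <- detect_quiet_standing(pq)
  expect_identical(nrow(spans), 1L)
  truth <- (recq$quiet_spans[1, ] - 1) %/% 3 + 1
  overlap <- max(0, min(spans$end[1], truth["end"]) -
                    max(spans$start[1], truth["start"]) + 1)
  expect_gte(overlap / (truth["end"] - truth["start"] + 1), 0.90)

  # a pure quiet recording is one span covering nearly everything
  quiet_only <- pq
  n <- 2000L
  quiet_only$hip_deg <- rnorm(n, 0, 0.05)
  quiet_only$knee_deg <- 5 + rnorm(n, 0, 0.05)
  quiet_only$emg <- matrix(abs(rnorm(4 * n, 0, 0.01)), 4)
  all_spans <- detect_quiet_standing(quiet_only)
  expect_identical(nrow(all_spans), 1L)
  expect_gte((all_spans$end[1] - all_spans$start[1] + 1) / n, 0.95)
})

test_that("event detection matches simulator truth on clean recordings", {
  rec <- simulate_subject(gait_sim_config(n_strides = 20, angle_noise_sd = 0,
                                          seed = 42), "S01")
  proc <- preprocess_pipeline(rec)
  ev <- detect_gait_events(proc)
  expect_true(all(ev$type[-1] != ev$type[-nrow(ev)]))
  truth <- proc$events  # simulator events mapped to the 500 Hz grid
  expect_identical(nrow(ev), nrow(truth))
  expect_identical(ev$type, truth$type)
  expect_true(all(abs(ev$sample - truth$sample) <= 2))
  expect_error(detect_gait_events(proc, theta_swing_on = 10, theta_stance_on = 15),
               class = "gaitphase_config_error")
})

test_that("event detection fails cleanly without gait and degrades gently with noise", {
  proc <- fix_processed()
  flat <- proc
  flat$knee_deg <- seq(0, 10, length.out = 3000)
  flat$hip_deg <- flat$knee_deg
  flat$emg <- proc$emg[, 1:3000]
  expect_error(detect_gait_events(flat), class = "gaitphase_data_error")

  clean <- preprocess_pipeline(
    simulate_subject(gait_sim_config(n_strides = 20, angle_noise_sd = 0, seed = 42), "S01"))
  errs <- unlist(lapply(1:3, function(rep) {
    noisy <- clean
    noisy$knee_deg <- withr::with_seed(rep, clean$knee_deg + rnorm(length(clean$knee_deg), 0, 0.5))
    ev <- detect_gait_events(noisy)
    vapply(seq_len(nrow(ev)), function(i) {
      same <- clean$events[clean$events$type == ev$type[i], ]
      min(abs(same$sample - ev$sample[i]))
    }, numeric(1))
  }))
  expect_lte(median(errs), 5)
})

test_that("events_to_labels assigns stance/swing half-open intervals", {
  tl <- tibble::tibble(sample = c(100L, 400L), type = c("HS", "TO"))
  track <- events_to_labels(tl, 500L)
  expect_identical(length(track$labels), 500L)
  expect_true(all(track$labels[100:399] == 1L))
  expect_true(all(track$labels[400:500] == 2L))
  expect_true(all(track$labels[1:99] == 2L))  # consistent with upcoming HS

  single <- events_to_labels(tibble::tibble(sample = 50L, type = "HS"), 200L)
  expect_true(all(single$labels[50:200] == 1L))

  expect_error(events_to_labels(tibble::tibble(sample = integer(0), type = character(0)), 10L),
               class = "gaitphase_data_error")
  expect_error(events_to_labels(tibble::tibble(sample = c(10L, 5L), type = c("HS", "TO")), 20L),
               class = "gaitphase_data_error")
  expect_error(events_to_labels(tibble::tibble(sample = c(5L, 10L), type = c("HS", "HS")), 20L),
               class = "gaitphase_data_error")
})

test_that("detected labels reproduce simulator truth after the 3:1 mapping", {
  rec <- simulate_subject(gait_sim_config(n_strides = 20, angle_noise_sd = 0,
                                          seed = 42), "S01")
  proc <- preprocess_pipeline(rec)
  track <- events_to_labels(detect_gait_events(proc), ncol(proc$emg))
  # identical except within +/-2 frames of each boundary
  mismatch <- which(track$labels != proc$labels)
  if (length(mismatch)) {
    d <- vapply(mismatch, function(t) min(abs(t - proc$events$sample)), numeric(1))
    expect_true(all(d <= 2))
  }
  expect_gt(mean(track$labels == proc$labels), 0.995)
})

test_that("label shift advances class changes and truncates the tail", {
  tl <- tibble::tibble(sample = c(100L, 300L), type = c("HS", "TO"))
  track <- events_to_labels(tl, 1000L)
  shifted <- shift_labels(track, 60L)
  expect_identical(length(shifted$labels), 940L)
  expect_identical(shifted$shift_frames, 60L)
  # change at 300 moves to 240
  expect_identical(shifted$labels[239], 1L)
  expect_identical(shifted$labels[240], 2L)
  expect_identical(shift_labels(track, 0L), track)
  expect_error(shift_labels(track, 1000L), class = "gaitphase_data_error")
})

test_that("shift equivariance: shifting labels equals shifting the timeline", {
  tl <- tibble::tibble(sample = c(100L, 300L, 500L, 750L),
                       type = c("HS", "TO", "HS", "TO"))
  k <- 60L
  a <- shift_labels(events_to_labels(tl, 1000L), k)
  tl_early <- dplyr::mutate(tl, sample = sample - k)
  b <- events_to_labels(tl_early, 1000L - k)
  expect_identical(a$labels, b$labels)
})

test_that("round trip: change-point extraction recovers the timeline", {
  tl <- tibble::tibble(sample = c(40L, 200L, 420L, 700L),
                       type = c("TO", "HS", "TO", "HS"))
  track <- events_to_labels(tl, 900L)
  chg <- which(diff(track$labels) != 0) + 1L
  types <- ifelse(track$labels[chg] == 1L, "HS", "TO")
  expect_identical(chg, tl$sample)
  expect_identical(types, tl$type)
})

test_that("windowing produces the right count, overlap and one-hot encoding", {
  proc <- fix_processed()
  n <- ncol(proc$emg)
  track <- events_to_labels(detect_gait_events(proc), n)
  ds <- make_sequences(proc, track)
  N <- dim(ds$x)[1]
  expect_identical(N, as.integer((min(n, length(track$labels)) - 500) %/% 50 + 1))
  expect_identical(diff(ds$window_start), rep(50L, N - 1))
  expect_equal(apply(ds$y, c(1, 3), sum), matrix(1, N, 500))
  expect_identical(dim(ds$x)[2:3], c(4L, 500L))
  # windows agree with the source signal
  expect_equal(ds$x[3, , ],
               unname(proc$emg[, ds$window_start[3]:(ds$window_start[3] + 499)]))

  # T' = 2000 gives N = 31; T' = 500 gives N = 1
  short <- proc
  short$emg <- proc$emg[, 1:2000]
  tshort <- events_to_labels(detect_gait_events(proc), 2000L)
  expect_identical(dim(make_sequences(short, tshort)$x)[1], 31L)
  tiny <- proc
  tiny$emg <- proc$emg[, 1:500]
  t500 <- structure(list(labels = track$labels[1:500], shift_frames = 0L, fs = 500),
                    class = "label_track")
  expect_identical(dim(make_sequences(tiny, t500)$x)[1], 1L)
  t100 <- structure(list(labels = track$labels[1:100], shift_frames = 0L, fs = 500),
                    class = "label_track")
  expect_error(make_sequences(tiny, t100), class = "gaitphase_data_error")
})

test_that("prepare_dataset windows active segments independently of quiet bouts", {
  rec <- simulate_subject(gait_sim_config(n_strides = 10,
                                          quiet_bouts = list(c(5, 5)),
                                          seed = 3), "S02")
  ds <- prepare_dataset(list(rec), shift_frames = 0L)
  proc <- preprocess_pipeline(rec)
  spans <- detect_quiet_standing(proc)
  # every window lies wholly inside one active segment: since window starts
  # are segment-relative, check none of the windows contains quiet frames by
  # construction of segment lengths
  expect_gt(dim(ds$x)[1], 0)
  expect_identical(ds$labeling_mode, "kinematics")
  # shifted variant is tagged and usable
  ds_sh <- prepare_dataset(list(rec), shift_frames = 60L)
  expect_identical(ds_sh$labeling_mode, "shifted")
  expect_lt(dim(ds_sh$x)[1], dim(ds$x)[1] + 1)
})

test_that("dataset binding and subsetting preserve the manifest", {
  ds <- fix_tiny_dataset()
  man <- dataset_manifest(ds)
  expect_identical(nrow(man), dim(ds$x)[1])
  sub <- subset_dataset(ds, 1:5)
  expect_identical(dim(sub$x)[1], 5L)
  expect_identical(sub$subject_ids, ds$subject_ids[1:5])
  again <- bind_datasets(list(sub, subset_dataset(ds, 6:8)))
  expect_identical(dim(again$x)[1], 8L)
  expect_equal(again$x[6, , ], ds$x[6, , ])
})
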