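cfg0 <- cohort_config(seed = 42)

test_that("a 120 bpm, 8-beat trial at 30 Hz spans 4 s with 15 frames per beat", {
  p <- subject_profile("S01", "A", 1.77)
  trial <- generate_motion_trial(p, build_combination_script(1), cfg0, seed = 5)
  expect_equal(length(trial$left$time), 121L)  # 120 intervals + shared endpoint
  expect_equal(trial$left$time[121], 4)
  expect_equal(trial$boundaries, seq(0L, 120L, by = 15L))
  expect_equal(trial$left$time, trial$right$time)
})

test_that("motion trials are bit-identical under the same seed", {
  p <- subject_profile("S01", "B", 1.80)
  s <- build_combination_script(2)
  t1 <- generate_motion_trial(p, s, cfg0, seed = 99)
  t2 <- generate_motion_trial(p, s, cfg0, seed = 99)
  expect_identical(t1$left$pos, t2$left$pos)
  expect_identical(t1$right$pos, t2$right$pos)
  t3 <- generate_motion_trial(p, s, cfg0, seed = 100)
  expect_false(identical(t1$left$pos, t3$left$pos))
})

test_that("noiseless path length is exactly linear in amplitude scale", {
  p <- subject_profile("S01", "A", 1.77)
  p$amp_factor <- 1
  s <- build_combination_script(1)
  mk <- function(amp) {
    cfg <- cohort_config(coord_noise_sd = 0, amplitude_scale = c(A = amp, B = 1),
                         seed = 1)
    generate_motion_trial(p, s, cfg, seed = 1)
  }
  l1 <- track_length(mk(1.0)$left)
  l11 <- track_length(mk(1.1)$left)
  expect_equal(l11, 1.1 * l1, tolerance = 1e-12)
})

test_that("rate too low for two frames per beat is a configuration error", {
  p <- subject_profile("S01", "A", 1.77)
  cfg <- cohort_config(frame_rate = 3, seed = 1)
  expect_error(generate_motion_trial(p, build_combination_script(1), cfg),
               "frame rate too low")
})

test_that("generated heights follow the stature distribution", {
  cfg <- cohort_config(n_group_a = 500, n_group_b = 500, seed = 2024)
  prof <- generate_cohort(cfg, combos = integer(0))$profiles
  expect_equal(nrow(prof), 1000L)
  expect_lt(abs(mean(prof$height) - 1.77), 0.02)
  expect_lt(abs(sd(prof$height) - 0.09), 0.02)
  expect_true(all(prof$height > 0))
  expect_gt(mean(prof$handedness == "right"), 0.8)
})

test_that("EMG channels are zero when all weights are zero and noise is off", {
  zero_w <- list(A = stats::setNames(rep(0, 8), emg_channels()),
                 B = stats::setNames(rep(0, 8), emg_channels()))
  cfg <- cohort_config(muscle_weights = zero_w, emg_noise_sd = 0,
                       activation_sd = 0, seed = 3)
  p <- subject_profile("S01", "A", 1.77)
  trial <- generate_motion_trial(p, build_combination_script(1), cfg, seed = 4)
  emg <- generate_emg_trial(trial, p, cfg, seed = 5)
  for (ch in emg_channels()) {
    expect_equal(emg_rms(emg$channels[[ch]]), 0)
  }
})

test_that("doubling one channel's weight doubles its RMS (same carrier realization)", {
  w1 <- default_muscle_weights()
  w2 <- w1
  w2$A["left_deltoid_middle"] <- 2 * w1$A["left_deltoid_middle"]
  p <- subject_profile("S01", "A", 1.77)
  mk <- function(w) {
    cfg <- cohort_config(muscle_weights = w, emg_noise_sd = 0,
                         activation_sd = 0, seed = 6)
    trial <- generate_motion_trial(p, build_combination_script(1), cfg, seed = 7)
    generate_emg_trial(trial, p, cfg, seed = 8)
  }
  e1 <- mk(w1); e2 <- mk(w2)
  expect_equal(emg_rms(e2$channels$left_deltoid_middle),
               2 * emg_rms(e1$channels$left_deltoid_middle), tolerance = 1e-12)
  # untouched channel unchanged
  expect_identical(e1$channels$right_biceps_brachii,
                   e2$channels$right_biceps_brachii)
})

test_that("group-A EMG is latissimus-dominant after MVIC standardization", {
  cfg <- cohort_config(seed = 11)
  p <- subject_profile("S01", "A", 1.77)
  trial <- generate_motion_trial(p, build_combination_script(1), cfg, seed = 12)
  emg <- generate_emg_trial(trial, p, cfg, seed = 13)
  mvic <- generate_mvic(p, cfg, seed = 14)
  m <- per_beat_emg(emg, emg$boundaries_s, mvic$reference)
  tw <- m[m$window == "trial", ]
  top <- tw$channel[which.max(tw$rms_pct)]
  expect_match(top, "latissimus_dorsi")
  expect_true(all(tw$rms_pct < 100))  # bounded by the MVIC reference
})

test_that("MVIC reference RMS recovers the constant envelope level", {
  # window = burst duration: the reference is the whole-burst RMS, which for a
  # constant envelope times a unit-variance carrier equals the envelope
  cfg <- cohort_config(emg_noise_sd = 0, seed = 21, mvic_duration_s = 10,
                       mvic_window_s = 10)
  p <- subject_profile("S01", "A", 1.77)
  mvic <- generate_mvic(p, cfg, seed = 22, envelope_level = 2.5)
  expect_equal(mean(mvic$reference$reference_rms), 2.5, tolerance = 0.001)
  # a shorter sliding window can only select an equal-or-higher RMS window
  cfg1 <- cohort_config(emg_noise_sd = 0, seed = 21, mvic_duration_s = 10,
                        mvic_window_s = 1)
  m1 <- generate_mvic(p, cfg1, seed = 22, envelope_level = 2.5)
  expect_true(all(m1$reference$reference_rms >= mvic$reference$reference_rms))
  # different seeds give different noise realizations
  mvic2 <- generate_mvic(p, cfg, seed = 23, envelope_level = 2.5)
  expect_false(identical(mvic$reference$reference_rms,
                         mvic2$reference$reference_rms))
})

test_that("generate_cohort produces the full bundle reproducibly", {
  cfg <- cohort_config(n_group_a = 2, n_group_b = 2, seed = 77,
                       mvic_duration_s = 1.5)
  c1 <- generate_cohort(cfg)
  expect_equal(nrow(c1$profiles), 4L)
  expect_length(c1$motion, 8L)   # 4 subjects x 2 combinations
  expect_length(c1$emg, 8L)
  expect_length(c1$mvic, 4L)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$profiles, c2$profiles)
  expect_identical(c1$motion$S01_c1$left$pos, c2$motion$S01_c1$left$pos)
  expect_identical(c1$emg$S03_c2$channels, c2$emg$S03_c2$channels)
  expect_identical(c1$mvic$S02$reference, c2$mvic$S02$reference)
  # MVIC bounds every task envelope for the subject
  for (id in names(c1$mvic)) {
    refs <- c1$mvic[[id]]$reference
    for (key in grep(paste0("^", id, "_"), names(c1$emg), value = TRUE)) {
      e <- c1$emg[[key]]
      m <- per_beat_emg(e, e$boundaries_s, refs)
      expect_true(all(m$rms_pct[m$window == "trial"] < 100))
    }
  }
})

test_that("invalid cohort configurations are rejected before generation", {
  expect_error(cohort_config(n_group_a = 0), "group sizes")
  expect_error(cohort_config(tempo = -1), "tempo")
  expect_error(cohort_config(amplitude_scale = c(A = 1)), "amplitude_scale")
  expect_error(cohort_config(coord_noise_sd = -0.1), "noise")
})
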