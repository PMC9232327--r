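test_that("track length handles stationary and collinear fixtures exactly", {
  fr <- 30
  still <- trajectory_series((0:4) / fr, matrix(1, 5, 3), fr)
  expect_equal(track_length(still), 0)
  line <- trajectory_series((0:2) / fr, rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), fr)
  expect_equal(track_length(line), 2)
  single <- structure(list(time = 0, pos = matrix(0, 1, 3), frame_rate = fr),
                      class = "trajectory_series")
  expect_error(track_length(single), "2 samples")
})

test_that("track and plane lengths match the brute-force oracle on random paths", {
  set.seed(42)
  for (i in 1:200) {
    tr <- random_trajectory(50)
    expect_equal(track_length(tr), brute_path_length(tr$pos),
                 tolerance = 1e-12)
    for (plane in c("XY", "XZ", "YZ")) {
      expect_equal(plane_track_length(tr, plane),
                   brute_plane_length(tr$pos, armbeat:::plane_columns(plane)),
                   tolerance = 1e-12)
      expect_lte(plane_track_length(tr, plane), track_length(tr) + 1e-12)
    }
  }
})

test_that("3D track length is invariant under rigid rotation and translation", {
  set.seed(7)
  for (i in 1:20) {
    tr <- random_trajectory(50)
    rot <- random_rotation()
    shift <- rnorm(3)
    moved <- trajectory_series(
      tr$time, t(rot %*% t(tr$pos)) + matrix(shift, 50, 3, byrow = TRUE),
      tr$frame_rate
    )
    expect_equal(track_length(moved), track_length(tr), tolerance = 1e-9)
  }
})

test_that("track length is additive over concatenation and stable under refinement", {
  set.seed(11)
  a <- matrix(runif(30), 10, 3)
  b <- matrix(runif(30), 10, 3)
  fr <- 30
  la <- track_length(trajectory_series((0:9) / fr, a, fr))
  lb <- track_length(trajectory_series((0:9) / fr, b, fr))
  lab <- track_length(trajectory_series((0:19) / fr, rbind(a, b), fr))
  joint <- sqrt(sum((b[1, ] - a[10, ])^2))
  expect_equal(lab, la + lb + joint, tolerance = 1e-12)

  # inserting a point on an existing segment leaves the length unchanged
  mid <- (a[4, ] + a[5, ]) / 2
  refined <- rbind(a[1:4, ], mid, a[5:10, ])
  expect_equal(track_length(trajectory_series((0:10) / fr, refined, fr)), la,
               tolerance = 1e-12)
  # an off-segment point never decreases it
  off <- mid + c(0.3, 0, 0)
  bent <- rbind(a[1:4, ], off, a[5:10, ])
  expect_gte(track_length(trajectory_series((0:10) / fr, bent, fr)), la)
})

test_that("pure vertical motion projects as expected onto the three planes", {
  fr <- 30
  tr <- trajectory_series((0:1) / fr, rbind(c(0, 0, 0), c(0, 0, 1)), fr)
  expect_equal(plane_track_length(tr, "XY"), 0)
  expect_equal(plane_track_length(tr, "XZ"), 1)
  expect_equal(plane_track_length(tr, "YZ"), 1)
  # planar confinement: z = const makes XY equal the full length
  flat <- trajectory_series((0:9) / fr, cbind(matrix(runif(20), 10, 2), 2), fr)
  expect_equal(plane_track_length(flat, "XY"), track_length(flat),
               tolerance = 1e-12)
})

test_that("relative track length is the plain ratio to height", {
  expect_equal(relative_track_length(6.076, 1.77), 6.076 / 1.77)
  expect_equal(round(relative_track_length(6.076, 1.77), 3), 3.433)
  expect_equal(relative_track_length(0, 1.8), 0)
  expect_equal(relative_track_length(1.8, 1.8), 1)
  expect_error(relative_track_length(1, 0), "height")
  expect_error(relative_track_length(1, -2), "height")
})

test_that("hand averaging is the arithmetic mean and is commutative", {
  fr <- 30
  l <- track_length_summary(random_trajectory(20), 1.8, "left", "S01")
  r <- track_length_summary(random_trajectory(20), 1.8, "right", "S01")
  avg <- hand_average(l, r)
  expect_equal(avg$length_m, (l$length_m + r$length_m) / 2)
  expect_equal(avg$hand, rep("averaged", 4))
  avg2 <- hand_average(r, l)
  expect_equal(avg$length_m, avg2$length_m)
  same <- hand_average(l, l)
  expect_equal(same$length_m, l$length_m)
  r_other <- r; r_other$subject_id <- "S02"
  expect_error(hand_average(l, r_other), "different subjects")
})

test_that("linear speed is exact for stationary and uniform motion", {
  fr <- 30
  still <- trajectory_series((0:9) / fr, matrix(3, 10, 3), fr)
  expect_equal(linear_speed(still)$speed, rep(0, 10))
  # 0.1 m per frame at 30 Hz -> 3 m/s, exact under central differences
  pos <- cbind(0.1 * (0:9), 0, 0)
  uni <- trajectory_series((0:9) / fr, pos, fr)
  expect_equal(linear_speed(uni)$speed, rep(3, 10), tolerance = 1e-12)
})

test_that("beat segmentation partitions the trial at rounded beat multiples", {
  expect_equal(segment_beats(120, 120, 30, 8), seq(0L, 120L, 15L))
  expect_equal(segment_beats(60, 120, 30, 4), seq(0L, 60L, 15L))
  b <- segment_beats(90, 100, 30, 5)
  expect_equal(b, as.integer(round((0:5) * 18)))
  expect_true(all(diff(b) > 0))
  expect_error(segment_beats(80, 120, 30, 8), "inconsistent")
})

test_that("braking metrics reproduce the 5-point fixture exactly", {
  fr <- 30
  sp <- structure(list(time = (0:4) / fr, speed = c(0, 1, 2, 1, 0),
                       frame_rate = fr), class = "speed_series")
  bm <- braking_metrics(sp, c(0L, 4L))
  expect_equal(bm$v_peak, 2)
  expect_equal(bm$t_peak, 2 / 30)
  expect_equal(bm$v_end, 0)
  expect_equal(bm$delta_v, -2)
  expect_equal(bm$delta_t, 2 / 30)
  expect_equal(bm$a_bar, -30)
  expect_false(bm$degenerate)
})

test_that("braking identity a_bar * delta_t == delta_v holds on generated trials", {
  cfg <- cohort_config(seed = 31)
  p <- subject_profile("S01", "A", 1.75)
  for (combo in 1:2) {
    trial <- generate_motion_trial(p, build_combination_script(combo), cfg,
                                   seed = combo)
    for (hand in c("left", "right")) {
      bm <- braking_metrics(linear_speed(trial[[hand]]), trial$boundaries)
      ok <- !bm$degenerate
      expect_true(all(ok))
      expect_equal(bm$a_bar[ok] * bm$delta_t[ok], bm$delta_v[ok],
                   tolerance = 1e-12)
      expect_true(all(bm$delta_v[ok] <= 0))
      # min-jerk beats end near rest: terminal speed well below the peak
      expect_true(all(bm$v_end[ok] < 0.2 * bm$v_peak[ok]))
    }
  }
})

test_that("a beat whose speed peaks at its final frame is flagged degenerate", {
  fr <- 30
  sp <- structure(list(time = (0:4) / fr, speed = c(0, 1, 2, 3, 4),
                       frame_rate = fr), class = "speed_series")
  expect_warning(bm <- braking_metrics(sp, c(0L, 4L)), "degenerate")
  expect_true(bm$degenerate)
  expect_true(is.na(bm$a_bar))
})

test_that("hand-averaged braking is the mean of the per-hand records", {
  fr <- 30
  mk <- function(vals) {
    structure(list(time = (0:4) / fr, speed = vals, frame_rate = fr),
              class = "speed_series")
  }
  l <- braking_metrics(mk(c(0, 1, 2, 1, 0)), c(0L, 4L))
  r <- braking_metrics(mk(c(0, 2, 4, 2, 0)), c(0L, 4L))
  avg <- braking_average(l, r)
  expect_equal(avg$delta_v, -3)
  expect_equal(avg$a_bar, -45)
})
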