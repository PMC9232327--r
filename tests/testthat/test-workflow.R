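test_that("simulate writes the full per-subject file set plus manifest", {
  dir <- withr_local_tempdir()
  cfg <- small_config(seed = 7)
  man <- simulate_cohort(cfg, dir)
  files <- list.files(dir)
  # 6 subjects x 2 combos x (trajectory + emg) + 6 mvic + manifest
  expect_equal(man$n_files, 6 * 2 * 2 + 6)
  expect_true("manifest.json" %in% files)
  expect_true(all(sprintf("S%02d_c1_trajectory.csv", 1:6) %in% files))
  expect_true(all(sprintf("S%02d_mvic.csv", 1:6) %in% files))
  # trajectory round-trips through the CSV schema
  hands <- read_trajectory_csv(file.path(dir, "S01_c1_trajectory.csv"),
                               frame_rate = cfg$frame_rate)
  expect_named(hands, c("left", "right"))
  expect_equal(length(hands$left$time), 121L)
})

test_that("simulate is byte-identical under one config and validates group sizes", {
  d1 <- withr_local_tempdir(); d2 <- withr_local_tempdir()
  cfg <- small_config(seed = 19)
  simulate_cohort(cfg, d1)
  simulate_cohort(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_error(cohort_config(n_group_a = 0, n_group_b = 5), "group sizes")
})

test_that("analyze produces the table schema of the protocol", {
  dir <- withr_local_tempdir(); out <- withr_local_tempdir()
  simulate_cohort(small_config(seed = 7), dir)
  man <- analyze_cohort(dir, out)
  s <- read.csv(file.path(out, "stats.csv"), stringsAsFactors = FALSE)
  # 3 plane rows (+ XYZ) per combo for track length
  for (combo in 1:2) {
    tl <- s[s$combo == combo & s$family == "track_length", ]
    expect_setequal(tl$key, c("XY", "XZ", "YZ", "XYZ"))
    rl <- s[s$combo == combo & s$family == "relative_track_length", ]
    expect_setequal(rl$key, c("XY", "XZ", "YZ", "XYZ"))
  }
  # 8 + 4 beat rows for braking
  expect_setequal(s$key[s$combo == 1 & s$family == "a_bar"], as.character(1:8))
  expect_setequal(s$key[s$combo == 2 & s$family == "a_bar"], as.character(1:4))
  # 8 channel rows x 2 combos for EMG
  for (combo in 1:2) {
    expect_setequal(s$key[s$combo == combo & s$family == "rms_pct"],
                    emg_channels())
  }
  expect_true(file.exists(file.path(out, "report.md")))
  expect_length(man$warnings, 0)
})

test_that("analyze isolates a corrupt subject file and logs it", {
  dir <- withr_local_tempdir(); out <- withr_local_tempdir()
  simulate_cohort(small_config(seed = 23), dir)
  writeLines("time_s,garbage\n0,x", file.path(dir, "S02_c1_emg.csv"))
  man <- analyze_cohort(dir, out)
  expect_true(any(grepl("S02", man$warnings)))
  emg <- read.csv(file.path(out, "emg.csv"), stringsAsFactors = FALSE)
  kin <- read.csv(file.path(out, "kinematics.csv"), stringsAsFactors = FALSE)
  expect_false("S02" %in% emg$subject_id[emg$combo == 1])
  expect_true("S02" %in% emg$subject_id[emg$combo == 2])
  expect_true("S02" %in% kin$subject_id[kin$combo == 1])
})

test_that("analyzing an empty directory fails fast without partial output", {
  dir <- withr_local_tempdir(); out <- file.path(withr_local_tempdir(), "o")
  expect_error(analyze_cohort(dir, out), "manifest")
  expect_false(file.exists(file.path(out, "stats.csv")))
})

test_that("report rendering is deterministic with conventional significance stars", {
  dir <- withr_local_tempdir(); out <- withr_local_tempdir()
  simulate_cohort(small_config(seed = 7), dir)
  analyze_cohort(dir, out)
  r1 <- readLines(file.path(out, "report.md"))
  render_report(out)
  r2 <- readLines(file.path(out, "report.md"))
  expect_identical(r1, r2)
  s <- read.csv(file.path(out, "stats.csv"), stringsAsFactors = FALSE)
  if (any(s$p < 0.05, na.rm = TRUE)) {
    expect_true(any(grepl("\\| \\*+ \\|", r1)))
  }
  # stars agree with the stats rows (XYZ totals are not rendered as table rows)
  starred <- sum(grepl("\\| \\*\\*? \\|", r1))
  rendered <- !(s$family %in% c("track_length", "relative_track_length") &
                  s$key == "XYZ")
  expect_equal(starred, sum(s$p[rendered] < 0.05, na.rm = TRUE))
})

test_that("run configs round-trip through YAML and drive the CLI dispatcher", {
  dir <- withr_local_tempdir()
  cfg_path <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(
    cohort = list(n_group_a = 2, n_group_b = 2, seed = 5,
                  amplitude_scale = list(A = 1.2, B = 1.0),
                  mvic_duration_s = 1.5),
    options = list(t_variant = "welch")
  ), cfg_path)
  run <- read_run_config(cfg_path)
  expect_equal(run$config$n_group_a, 2L)
  expect_equal(unname(run$config$amplitude_scale["A"]), 1.2)
  expect_equal(run$options$t_variant, "welch")
  out <- file.path(dir, "sim")
  expect_message(armbeat_cli(c("simulate", "--config", cfg_path, "--out", out)),
                 "written")
  expect_true(file.exists(file.path(out, "manifest.json")))
  an <- file.path(dir, "an")
  expect_message(armbeat_cli(c("analyze", "--in", out, "--out", an)), "written")
  expect_true(file.exists(file.path(an, "report.md")))
  expect_error(armbeat_cli(c("simulate")), "--out")
  expect_error(armbeat_cli("nonsense"), "unknown command")
})
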