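#' Default per-channel muscle-weight profiles
#'
#' Relative activation weights of the 8 channels for the two groups. The
#' base per-muscle weights encode the groups' muscle-use patterns: group A
#' is latissimus-dorsi dominant bilaterally; group B relies on the left
#' triceps and right biceps. Right-side channels are multiplied by
#' `side_asymmetry` (dominant-hand effect, right > left).
#'
#' @param side_asymmetry multiplicative factor applied to right-side
#'   channels (>= 1 encodes right-hand dominance).
#' @return Named list with elements `A` and `B`, each a named numeric
#'   vector over [emg_channels()].
#' @export
default_muscle_weights <- function(side_asymmetry = 1.3) {
  ch <- emg_channels()
  base <- list(
    A = c(left_biceps_brachii = 0.30, left_triceps_brachii = 0.40,
          left_deltoid_middle = 0.50, left_latissimus_dorsi = 1.00,
          right_biceps_brachii = 0.30, right_triceps_brachii = 0.40,
          right_deltoid_middle = 0.50, right_latissimus_dorsi = 1.00),
    B = c(left_biceps_brachii = 0.30, left_triceps_brachii = 0.85,
          left_deltoid_middle = 0.50, left_latissimus_dorsi = 0.35,
          right_biceps_brachii = 0.85, right_triceps_brachii = 0.35,
          right_deltoid_middle = 0.50, right_latissimus_dorsi = 0.35)
  )
  lapply(base, function(w) {
    w[grep("^right_", names(w))] <- w[grep("^right_", names(w))] * side_asymmetry
    w[ch]
  })
}

#' Synthetic-cohort configuration
#'
#' All parameters of the seeded synthetic study: group sizes, sampling
#' rates, tempo, per-group amplitude and braking profiles, per-channel
#' muscle weights and noise levels. Defaults emulate the study conditions:
#' 15 athletes split 4/11, stature Normal(1.77, 0.09^2) m, capture at
#' 30 Hz, sEMG at 1000 Hz, metronome at 120 beats/min.
#'
#' @param n_group_a,n_group_b group sizes (positive integers).
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#' @param frame_rate motion-capture rate, Hz.
#' @param emg_rate EMG sampling rate, Hz.
#' @param tempo metronome tempo, beats/min.
#' @param height_mean,height_sd stature distribution (m), truncated > 0.
#' @param amplitude_scale named vector `c(A=, B=)` of dimensionless
#'   movement-amplitude scales.
#' @param subject_amp_sd SD of the per-subject amplitude factor (drawn
#'   Normal(1, sd^2), truncated positive): individual technique
#'   variability on top of the group scale.
#' @param braking_sharpness named vector `c(A=, B=)`: time-warp exponents
#'   (> 0) applied to the minimum-jerk progress profile; values > 1 delay
#'   the speed peak and sharpen terminal braking.
#' @param muscle_weights per-group named channel-weight vectors, see
#'   [default_muscle_weights()].
#' @param side_asymmetry right/left activation factor used when building
#'   default weights.
#' @param coord_noise_sd additive coordinate noise SD (m).
#' @param emg_noise_sd additive EMG noise SD (mV).
#' @param activation_sd SD of the per-trial, per-channel multiplicative
#'   activation gain (Normal(1, sd^2), truncated positive): how strongly a
#'   subject recruits a muscle in the task relative to their MVIC. This is
#'   the between-subject variability that survives MVIC standardization.
#' @param emg_band EMG carrier bandwidth (Hz).
#' @param mvic_headroom MVIC envelope level relative to the nominal peak
#'   task envelope (> 1 keeps standardized task values bounded).
#' @param mvic_duration_s MVIC burst duration (s).
#' @param mvic_window_s sliding-window length for the MVIC reference (s).
#' @param prob_right_handed probability a subject is right-handed.
#' @param geometry an [arm_geometry()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_group_a = 4, n_group_b = 11, seed = 1,
                          frame_rate = 30, emg_rate = 1000, tempo = 120,
                          height_mean = 1.77, height_sd = 0.09,
                          amplitude_scale = c(A = 1.05, B = 1.00),
                          subject_amp_sd = 0.05,
                          braking_sharpness = c(A = 1.1, B = 1.0),
                          muscle_weights = NULL,
                          side_asymmetry = 1.3,
                          coord_noise_sd = 0.003,
                          emg_noise_sd = 0.02,
                          activation_sd = 0.15,
                          emg_band = c(20, 450),
                          mvic_headroom = 1.4,
                          mvic_duration_s = 3,
                          mvic_window_s = 1,
                          prob_right_handed = 0.9,
                          geometry = arm_geometry()) {
  cfg <- structure(
    list(
      n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
      seed = as.integer(seed), frame_rate = frame_rate, emg_rate = emg_rate,
      tempo = tempo, height_mean = height_mean, height_sd = height_sd,
      amplitude_scale = amplitude_scale,
      subject_amp_sd = subject_amp_sd,
      braking_sharpness = braking_sharpness,
      muscle_weights = muscle_weights %||% default_muscle_weights(side_asymmetry),
      side_asymmetry = side_asymmetry,
      coord_noise_sd = coord_noise_sd, emg_noise_sd = emg_noise_sd,
      activation_sd = activation_sd,
      emg_band = emg_band, mvic_headroom = mvic_headroom,
      mvic_duration_s = mvic_duration_s, mvic_window_s = mvic_window_s,
      prob_right_handed = prob_right_handed, geometry = geometry
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_group_a < 1L || cfg$n_group_b < 1L) {
    stop_invalid("group sizes must be positive")
  }
  for (field in c("frame_rate", "emg_rate", "tempo", "height_mean", "height_sd",
                  "mvic_headroom", "mvic_duration_s", "mvic_window_s")) {
    if (!is_scalar_number(cfg[[field]]) || cfg[[field]] <= 0) {
      stop_invalid("`", field, "` must be a positive number")
    }
  }
  for (field in c("amplitude_scale", "braking_sharpness")) {
    v <- cfg[[field]]
    if (!all(c("A", "B") %in% names(v)) || any(v <= 0)) {
      stop_invalid("`", field, "` must be positive and named for groups A and B")
    }
  }
  for (g in c("A", "B")) {
    w <- cfg$muscle_weights[[g]]
    if (is.null(w) || !all(emg_channels() %in% names(w))) {
      stop_invalid("muscle_weights$", g, " must name all 8 channels")
    }
    if (any(w < 0)) stop_invalid("muscle weights must be nonnegative")
  }
  if (cfg$coord_noise_sd < 0 || cfg$emg_noise_sd < 0 ||
      cfg$subject_amp_sd < 0 || cfg$activation_sd < 0) {
    stop_invalid("noise SDs must be nonnegative")
  }
  invisible(cfg)
}

#' Subject profile
#'
#' @param subject_id identifier string.
#' @param group `"A"` or `"B"`.
#' @param height stature in meters (> 0).
#' @param handedness `"left"` or `"right"`.
#' @return A one-row data.frame.
#' @export
subject_profile <- function(subject_id, group, height, handedness = "right") {
  if (!group %in% c("A", "B")) stop_invalid("`group` must be 'A' or 'B'")
  if (!is_scalar_number(height) || height <= 0) {
    stop_invalid("`height` must be a positive number")
  }
  if (!handedness %in% c("left", "right")) {
    stop_invalid("`handedness` must be 'left' or 'right'")
  }
  data.frame(subject_id = subject_id, group = group, height = height,
             handedness = handedness, stringsAsFactors = FALSE)
}

# Draw subject profiles for a cohort (heights truncated positive).
generate_profiles <- function(config) {
  n <- config$n_group_a + config$n_group_b
  local_seed(config$seed, {
    heights <- rnorm(n, config$height_mean, config$height_sd)
    while (any(heights <= 0)) {
      bad <- heights <= 0
      heights[bad] <- rnorm(sum(bad), config$height_mean, config$height_sd)
    }
    handed <- ifelse(runif(n) < config$prob_right_handed, "right", "left")
    amp <- rnorm(n, 1, config$subject_amp_sd)
    while (any(amp <= 0)) {
      bad <- amp <= 0
      amp[bad] <- rnorm(sum(bad), 1, config$subject_amp_sd)
    }
    data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      group = rep(c("A", "B"), c(config$n_group_a, config$n_group_b)),
      height = heights,
      handedness = handed,
      amp_factor = amp,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate one subject's motion trial
#'
#' Builds the beat-chained hand trajectories of a combination for one
#' subject: each beat is a minimum-jerk segment between its via-points
#' (time-warped by the group's `braking_sharpness` exponent), the whole
#' geometry is scaled by `amplitude_scale[group] * height / reference
#' height`, and zero-mean Gaussian coordinate noise is added. Each beat
#' occupies `60 / tempo` seconds; the trial has
#' `round(n_beats * (60/tempo) * frame_rate)` inter-frame intervals.
#'
#' @param profile one-row subject data.frame ([subject_profile()]).
#' @param script a [build_combination_script()].
#' @param config a [cohort_config()].
#' @param seed integer seed for this trial's noise.
#' @return An object of class `motion_trial`: `subject`, `combo_id`,
#'   `left` and `right` [trajectory_series], 0-based beat `boundaries`,
#'   `tempo`.
#' @export
generate_motion_trial <- function(profile, script, config, seed = config$seed) {
  fr <- config$frame_rate
  n_beats <- script$n_beats
  beat_dur <- 60 / script$tempo
  nf <- round(n_beats * beat_dur * fr)
  boundaries <- segment_beats(nf, script$tempo, fr, n_beats)
  if (any(diff(boundaries) < 2L)) {
    stop_invalid("frame rate too low: fewer than 2 frames per beat")
  }
  group <- profile$group
  amp_factor <- if (!is.null(profile$amp_factor)) profile$amp_factor else 1
  scale <- unname(config$amplitude_scale[group]) * amp_factor *
    profile$height / config$geometry$reference_height
  gamma <- unname(config$braking_sharpness[group])
  time <- (0:nf) / fr
  build_hand <- function(hand) {
    pos <- matrix(0, nf + 1L, 3L)
    start0 <- script$beats[[1]][[paste0(hand, "_start")]]
    for (k in seq_len(n_beats)) {
      b <- script$beats[[k]]
      qs <- start0 + scale * (b[[paste0(hand, "_start")]] - start0)
      qe <- start0 + scale * (b[[paste0(hand, "_end")]] - start0)
      idx <- (boundaries[k] + 1L):(boundaries[k + 1L] + 1L)
      tau <- (idx - 1L - boundaries[k]) / (boundaries[k + 1L] - boundaries[k])
      s <- min_jerk_profile(tau^gamma)
      pos[idx, ] <- outer(rep(1, length(idx)), qs) + outer(s, qe - qs)
    }
    pos
  }
  left <- build_hand("left")
  right <- build_hand("right")
  local_seed(seed, {
    if (config$coord_noise_sd > 0) {
      left <- left + matrix(rnorm(length(left), 0, config$coord_noise_sd),
                            nrow(left), 3L)
      right <- right + matrix(rnorm(length(right), 0, config$coord_noise_sd),
                              nrow(right), 3L)
    }
  })
  structure(
    list(
      subject = profile, combo_id = script$combo_id,
      left = trajectory_series(time, left, fr),
      right = trajectory_series(time, right, fr),
      boundaries = boundaries, tempo = script$tempo
    ),
    class = "motion_trial"
  )
}

# Unit-variance band-limited Gaussian carrier (the synthetic sEMG carrier;
# 20-450 Hz is the conventional surface-EMG bandwidth).
bandlimited_carrier <- function(n, rate, band) {
  x <- rnorm(n)
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, x)
  x <- x - mean(x)
  x / sd(x)
}

# Per-hand speed envelope resampled to the EMG rate.
speed_envelope <- function(motion, emg_times, smooth_window = 0) {
  lapply(c(left = "left", right = "right"), function(hand) {
    sp <- linear_speed(motion[[hand]], smooth_window)
    approx(sp$time, sp$speed, xout = emg_times, rule = 2)$y
  })
}

#' Generate one subject's EMG trial
#'
#' Synthesizes the 8 sEMG channels aligned to a motion trial. Each
#' channel's envelope is the instantaneous speed of its hand (resampled to
#' the EMG rate) times the group's channel weight (side asymmetry is
#' already folded into the per-channel weights) times a per-trial
#' activation gain (`activation_sd`); the signal is
#' `envelope * carrier + noise` with a unit-variance 20–450 Hz Gaussian
#' carrier and additive Gaussian noise.
#'
#' @param motion a `motion_trial`.
#' @param profile the subject's profile row.
#' @param config a [cohort_config()].
#' @param seed integer seed for carriers and noise.
#' @return An EMG trial: list with `subject`, `combo_id`, `channels`
#'   (named list over [emg_channels()]), `rate`, `duration_s`,
#'   `boundaries_s`. Class `emg_trial`.
#' @export
generate_emg_trial <- function(motion, profile, config, seed = config$seed) {
  rate <- config$emg_rate
  duration <- motion$left$time[n_frames(motion$left)]
  n <- round(duration * rate)
  times <- (0:(n - 1L)) / rate
  weights <- config$muscle_weights[[profile$group]]
  env <- speed_envelope(motion, times)
  generated <- local_seed(seed, {
    gains <- rep(1, length(emg_channels()))
    names(gains) <- emg_channels()
    if (config$activation_sd > 0) {
      gains[] <- rnorm(length(gains), 1, config$activation_sd)
      while (any(gains <= 0)) {
        bad <- gains <= 0
        gains[bad] <- rnorm(sum(bad), 1, config$activation_sd)
      }
    }
    out <- list()
    for (ch in emg_channels()) {
      w <- weights[[ch]]
      if (is.null(w) || is.na(w)) stop_invalid("missing weight for channel ", ch)
      hand <- if (startsWith(ch, "left_")) "left" else "right"
      carrier <- bandlimited_carrier(n, rate, config$emg_band)
      noise <- if (config$emg_noise_sd > 0) {
        rnorm(n, 0, config$emg_noise_sd)
      } else {
        numeric(n)
      }
      out[[ch]] <- env[[hand]] * w * gains[[ch]] * carrier + noise
    }
    list(channels = out, gains = gains)
  })
  structure(
    list(subject = profile, combo_id = motion$combo_id,
         channels = generated$channels, gains = generated$gains,
         rate = rate, duration_s = duration,
         boundaries_s = motion$boundaries / config$frame_rate),
    class = "emg_trial"
  )
}

# Nominal MVIC envelope level: headroom x the largest channel weight x the
# largest peak hand speed any subject is expected to reach (min-jerk peak
# 15 d / (8 T) over the longest beat chord, at the largest amplitude scale).
mvic_envelope_level <- function(config) {
  beat_dur <- 60 / config$tempo
  max_chord <- 0
  for (combo in 1:2) {
    script <- build_combination_script(combo, config$tempo, config$geometry)
    for (b in script$beats) {
      max_chord <- max(max_chord,
                       sqrt(sum((b$left_end - b$left_start)^2)),
                       sqrt(sum((b$right_end - b$right_start)^2)))
    }
  }
  v_nom <- 15 * max_chord * max(config$amplitude_scale) / (8 * beat_dur)
  config$mvic_headroom * v_nom * max(unlist(config$muscle_weights))
}

#' Generate a subject's MVIC reference trials
#'
#' Simulates one maximum-voluntary-isometric-contraction burst per channel
#' (constant envelope times the unit-variance carrier, plus noise) and
#' derives the per-channel standardization references with
#' [mvic_reference()]. The envelope level is a population-level constant
#' (see [cohort_config()]'s `mvic_headroom`), raised if needed so it
#' exceeds the subject's largest task envelope — standardized task values
#' stay bounded.
#'
#' @param profile the subject's profile row.
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param envelope_level optional per-subject envelope override (mV).
#' @return List with `subject`, `series` (named list of [emg_series]),
#'   `reference` (data.frame `channel`, `reference_rms`,
#'   `reference_meanabs`) and `envelope_level`. Class `mvic_trial`.
#' @export
generate_mvic <- function(profile, config, seed = config$seed,
                          envelope_level = NULL) {
  level <- envelope_level %||% mvic_envelope_level(config)
  rate <- config$emg_rate
  n <- round(config$mvic_duration_s * rate)
  series <- local_seed(seed, {
    out <- list()
    for (ch in emg_channels()) {
      carrier <- bandlimited_carrier(n, rate, config$emg_band)
      noise <- if (config$emg_noise_sd > 0) {
        rnorm(n, 0, config$emg_noise_sd)
      } else {
        numeric(n)
      }
      out[[ch]] <- emg_series(level * carrier + noise, rate, ch)
    }
    out
  })
  refs <- lapply(series, mvic_reference, window_s = config$mvic_window_s)
  structure(
    list(subject = profile, series = series, reference = mvic_ref_table(refs),
         envelope_level = level),
    class = "mvic_trial"
  )
}

#' Generate a full synthetic cohort
#'
#' Draws subject profiles and generates, for every subject and requested
#' combination, the motion trial, the aligned EMG trial and a per-subject
#' MVIC reference set. Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param combos which combinations to generate (subset of `c(1, 2)`;
#'   `integer(0)` generates profiles only).
#' @param include_emg generate EMG and MVIC trials (set `FALSE` for
#'   kinematics-only studies; much faster).
#' @return An object of class `cohort`: list with `config`, `profiles`,
#'   `scripts`, `motion` (named `subjectid_c<combo>`), `emg`, `mvic`
#'   (named by subject id).
#' @export
generate_cohort <- function(config, combos = c(1L, 2L), include_emg = TRUE) {
  validate_cohort_config(config)
  profiles <- generate_profiles(config)
  scripts <- lapply(combos, build_combination_script,
                    tempo = config$tempo, geometry = config$geometry)
  names(scripts) <- as.character(combos)
  motion <- list()
  emg <- list()
  mvic <- list()
  nominal_level <- if (include_emg && length(combos)) mvic_envelope_level(config)
  for (i in seq_len(nrow(profiles))) {
    profile <- profiles[i, ]
    max_env <- 0
    for (combo in combos) {
      key <- sprintf("%s_c%d", profile$subject_id, combo)
      trial <- generate_motion_trial(
        profile, scripts[[as.character(combo)]], config,
        seed = derive_seed(config$seed, i, combo, 1L)
      )
      motion[[key]] <- trial
      if (include_emg) {
        et <- generate_emg_trial(
          trial, profile, config, seed = derive_seed(config$seed, i, combo, 2L)
        )
        emg[[key]] <- et
        w <- config$muscle_weights[[profile$group]]
        for (ch in emg_channels()) {
          hand <- if (startsWith(ch, "left_")) "left" else "right"
          max_env <- max(max_env, w[[ch]] * et$gains[[ch]] *
                           max(linear_speed(trial[[hand]])$speed))
        }
      }
    }
    if (include_emg && length(combos)) {
      mvic[[profile$subject_id]] <- generate_mvic(
        profile, config, seed = derive_seed(config$seed, i, 0L, 3L),
        envelope_level = max(nominal_level, 1.05 * max_env)
      )
    }
  }
  structure(
    list(config = config, profiles = profiles, scripts = scripts,
         motion = motion, emg = emg, mvic = mvic),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d subjects (A: %d, B: %d), %d motion trials, %d EMG trials, seed %d\n",
    nrow(x$profiles), sum(x$profiles$group == "A"), sum(x$profiles$group == "B"),
    length(x$motion), length(x$emg), x$config$seed
  ))
  invisible(x)
}
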