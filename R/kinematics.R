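#' Action-track length of a 3D trajectory
#'
#' Cumulative Euclidean length of the sampled hand path: the distance from
#' each coordinate point to the next, summed over the whole movement. Used
#' as the amplitude index of a beat-paced arm movement.
#'
#' @param traj a [trajectory_series].
#' @return Path length in meters (0 for a stationary trajectory).
#' @export
track_length <- function(traj) {
  pos <- traj$pos
  if (nrow(pos) < 2L) stop_invalid("track_length needs at least 2 samples")
  d <- diff(pos)
  sum(sqrt(rowSums(d^2)))
}

#' Track length projected onto an anatomical plane
#'
#' Path length of the trajectory with one coordinate dropped: `XY`
#' (horizontal plane), `XZ` (frontal plane) or `YZ` (sagittal plane).
#' Always at most the full 3D track length, with equality only for motion
#' confined to that plane.
#'
#' @param traj a [trajectory_series].
#' @param plane one of `"XY"`, `"XZ"`, `"YZ"`.
#' @return Projected path length in meters.
#' @export
plane_track_length <- function(traj, plane) {
  pos <- traj$pos
  if (nrow(pos) < 2L) stop_invalid("plane_track_length needs at least 2 samples")
  d <- diff(pos[, plane_columns(plane), drop = FALSE])
  sum(sqrt(rowSums(d^2)))
}

#' Height-normalized relative track length
#'
#' Ratio of action-track length to subject stature, removing body-size
#' effects when comparing movement amplitude across subjects.
#'
#' @param length track length (m).
#' @param height subject stature (m, > 0).
#' @return Dimensionless ratio `length / height`.
#' @export
relative_track_length <- function(length, height) {
  if (!is_scalar_number(height) || height <= 0) {
    stop_invalid("`height` must be a positive number")
  }
  if (any(length < 0)) stop_invalid("`length` must be nonnegative")
  length / height
}

#' Per-plane track-length summary for one hand
#'
#' Computes the full 3D track length, the three plane projections and
#' their height-normalized relative values for one hand's trajectory.
#'
#' @param traj a [trajectory_series].
#' @param height subject stature (m).
#' @param hand `"left"`, `"right"` or `"averaged"`.
#' @param subject_id optional subject identifier carried through.
#' @return A data.frame with one row per plane (`XY`, `XZ`, `YZ`, `XYZ`)
#'   and columns `subject_id`, `hand`, `plane`, `length_m`,
#'   `relative_length`.
#' @export
track_length_summary <- function(traj, height, hand = "averaged",
                                 subject_id = NA_character_) {
  lengths <- c(
    XY = plane_track_length(traj, "XY"),
    XZ = plane_track_length(traj, "XZ"),
    YZ = plane_track_length(traj, "YZ"),
    XYZ = track_length(traj)
  )
  data.frame(
    subject_id = subject_id,
    hand = hand,
    plane = names(lengths),
    length_m = unname(lengths),
    relative_length = unname(relative_track_length(lengths, height)),
    stringsAsFactors = FALSE
  )
}

#' Average the left- and right-hand track-length summaries
#'
#' Arithmetic mean of the per-plane lengths (and relative lengths) of the
#' two hands, the convention used to report one amplitude value per subject.
#'
#' @param left,right data.frames from [track_length_summary()] for the same
#'   subject.
#' @return A summary data.frame with `hand = "averaged"`.
#' @export
hand_average <- function(left, right) {
  if (!identical(left$plane, right$plane)) {
    stop_invalid("left and right summaries must cover the same planes")
  }
  if (!isTRUE(all(is.na(c(left$subject_id, right$subject_id)))) &&
      !identical(left$subject_id, right$subject_id)) {
    stop_invalid("left and right summaries belong to different subjects")
  }
  out <- left
  out$hand <- "averaged"
  out$length_m <- (left$length_m + right$length_m) / 2
  out$relative_length <- (left$relative_length + right$relative_length) / 2
  out
}

#' Linear speed of a trajectory
#'
#' Scalar speed per frame from finite-difference velocity: central
#' differences at interior frames (exact for motion affine in time) and
#' one-sided differences at the first and last frame. An optional
#' moving-average smoothing of the speed series is available for noisy
#' capture data; it is off by default.
#'
#' @param traj a [trajectory_series] with at least 3 samples.
#' @param smooth_window odd moving-average window length in frames applied
#'   to the speed series; `0` or `1` disables smoothing.
#' @return An object of class `speed_series`: list with `time`, `speed`
#'   (m/s, nonnegative, same length as the trajectory) and `frame_rate`.
#' @export
linear_speed <- function(traj, smooth_window = 0) {
  pos <- traj$pos
  n <- nrow(pos)
  if (n < 3L) stop_invalid("linear_speed needs at least 3 samples")
  fr <- traj$frame_rate
  vel <- matrix(0, n, 3L)
  vel[1, ] <- (pos[2, ] - pos[1, ]) * fr
  vel[n, ] <- (pos[n, ] - pos[n - 1L, ]) * fr
  vel[2:(n - 1L), ] <- (pos[3:n, ] - pos[1:(n - 2L), ]) * (fr / 2)
  speed <- sqrt(rowSums(vel^2))
  if (smooth_window > 1) {
    w <- as.integer(smooth_window)
    if (w %% 2L == 0L) stop_invalid("`smooth_window` must be odd")
    k <- (w - 1L) %/% 2L
    padded <- c(rep(speed[1], k), speed, rep(speed[n], k))
    speed <- stats::filter(padded, rep(1 / w, w), sides = 2)[(k + 1L):(k + n)]
    speed <- as.numeric(speed)
  }
  structure(
    list(time = traj$time, speed = speed, frame_rate = fr),
    class = "speed_series"
  )
}

#' Beat boundaries of a metronome-paced trial
#'
#' Partitions a trial of `n_frames` inter-frame intervals into `n_beats`
#' metronome beats. Boundaries are 0-based frame offsets at rounded
#' multiples of the per-beat frame count `(60 / tempo) * frame_rate`, with
#' the first boundary at 0 and the last at `n_frames`.
#'
#' @param n_frames number of inter-frame intervals in the trial (the trial
#'   has `n_frames + 1` samples).
#' @param tempo metronome tempo, beats per minute.
#' @param frame_rate capture rate, Hz.
#' @param n_beats number of beats.
#' @return Integer vector of `n_beats + 1` strictly increasing 0-based
#'   boundary frame offsets.
#' @export
segment_beats <- function(n_frames, tempo, frame_rate, n_beats) {
  if (n_beats < 1L) stop_invalid("`n_beats` must be >= 1")
  if (n_frames < n_beats) stop_invalid("fewer frames than beats")
  step <- (60 / tempo) * frame_rate
  expected <- round(n_beats * step)
  if (abs(expected - n_frames) > 1) {
    stop_invalid(sprintf(
      "frame count %d inconsistent with %d beats at %g bpm / %g Hz (expected %d)",
      n_frames, n_beats, tempo, frame_rate, expected
    ))
  }
  b <- round((0:n_beats) * step)
  b[n_beats + 1L] <- n_frames
  if (any(diff(b) < 1)) stop_invalid("beat boundaries are not strictly increasing")
  as.integer(b)
}

#' Per-beat braking metrics from a speed series
#'
#' For each beat, locates the in-beat speed peak and measures the
#' deceleration ("braking") phase from that peak to the earlier of the
#' first post-peak frame where speed drops to (or below) `zero_threshold`
#' and the beat's final frame. Reports the speed drop
#' `delta_v = v_end - v_peak` (nonpositive; the minus sign only marks
#' deceleration) and the mean acceleration `a_bar = delta_v / delta_t`.
#' Beats whose speed peak falls on the final frame have no deceleration
#' phase; they are flagged `degenerate` (with a warning) and should be
#' excluded from group summaries.
#'
#' @param speed a `speed_series` from [linear_speed()].
#' @param boundaries 0-based beat boundary frame offsets from
#'   [segment_beats()].
#' @param zero_threshold speed (m/s) at or below which the hand is
#'   considered stopped.
#' @return A data.frame with one row per beat: `beat_index`, `t_peak`,
#'   `v_peak`, `t_end`, `v_end`, `delta_v`, `delta_t`, `a_bar`,
#'   `degenerate`. For degenerate beats the braking fields are `NA`.
#' @export
braking_metrics <- function(speed, boundaries, zero_threshold = 1e-3) {
  n <- length(speed$speed)
  boundaries <- as.integer(boundaries)
  if (boundaries[1] != 0L || boundaries[length(boundaries)] != n - 1L) {
    stop_invalid("boundaries must span the series: first 0, last n_samples - 1")
  }
  n_beats <- length(boundaries) - 1L
  rows <- vector("list", n_beats)
  for (k in seq_len(n_beats)) {
    idx <- (boundaries[k] + 1L):(boundaries[k + 1L] + 1L)
    sp <- speed$speed[idx]
    tm <- speed$time[idx]
    peak <- which.max(sp)
    if (peak == length(idx)) {
      warning(sprintf("beat %d: speed peak at beat end, no deceleration phase (degenerate)", k),
              call. = FALSE)
      rows[[k]] <- data.frame(
        beat_index = k, t_peak = tm[peak], v_peak = sp[peak],
        t_end = NA_real_, v_end = NA_real_, delta_v = NA_real_,
        delta_t = NA_real_, a_bar = NA_real_, degenerate = TRUE
      )
      next
    }
    post <- (peak + 1L):length(idx)
    stopped <- post[sp[post] <= zero_threshold]
    end <- if (length(stopped)) stopped[1] else length(idx)
    delta_v <- sp[end] - sp[peak]
    delta_t <- tm[end] - tm[peak]
    rows[[k]] <- data.frame(
      beat_index = k, t_peak = tm[peak], v_peak = sp[peak],
      t_end = tm[end], v_end = sp[end], delta_v = delta_v,
      delta_t = delta_t, a_bar = delta_v / delta_t, degenerate = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Average braking metrics across hands
#'
#' Arithmetic mean of `delta_v` and `a_bar` (and the descriptive speed
#' fields) of the two hands per beat, the convention used to report one
#' braking value per subject and beat. Beats degenerate on either hand are
#' flagged degenerate in the average.
#'
#' @param left,right data.frames from [braking_metrics()] over the same
#'   beats.
#' @return A data.frame with the same columns, hand-averaged.
#' @export
braking_average <- function(left, right) {
  if (!identical(left$beat_index, right$beat_index)) {
    stop_invalid("left and right braking records must cover the same beats")
  }
  out <- left
  for (col in c("t_peak", "v_peak", "t_end", "v_end", "delta_v", "delta_t", "a_bar")) {
    out[[col]] <- (left[[col]] + right[[col]]) / 2
  }
  out$degenerate <- left$degenerate | right$degenerate
  out
}
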