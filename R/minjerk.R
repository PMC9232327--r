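#' Minimum-jerk progress profile
#'
#' The quintic minimum-jerk position profile
#' `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5` on `tau` in `[0, 1]`: it starts
#' and ends at rest (zero velocity and acceleration at both boundaries) and
#' peaks in speed at `tau = 1/2` with `max ds/dtau = 15/8`.
#'
#' @param tau numeric vector of normalized times in `[0, 1]`.
#' @return Normalized displacement fraction in `[0, 1]`.
#' @export
min_jerk_profile <- function(tau) {
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Minimum-jerk point-to-point segment
#'
#' Generates a straight-line movement from `p0` to `p1` following the
#' minimum-jerk profile, the standard smooth point-to-point model for
#' reaching-type arm movements. The peak speed along the segment is
#' `15 d / (8 T)` for distance `d` and duration `T`.
#'
#' @param p0,p1 numeric length-3 start and end positions (m).
#' @param duration segment duration in seconds (> 0).
#' @param rate sampling rate in Hz (> 0).
#' @return A [trajectory_series] with `round(duration * rate) + 1` samples
#'   spanning `[0, duration]`.
#' @export
min_jerk_segment <- function(p0, p1, duration, rate) {
  if (!is_scalar_number(duration) || duration <= 0) {
    stop_invalid("`duration` must be a positive number")
  }
  if (!is_scalar_number(rate) || rate <= 0) {
    stop_invalid("`rate` must be a positive number")
  }
  p0 <- as.numeric(p0)
  p1 <- as.numeric(p1)
  if (length(p0) != 3L || length(p1) != 3L) {
    stop_invalid("`p0` and `p1` must be 3D positions")
  }
  n <- round(duration * rate)
  if (n < 1) stop_invalid("duration * rate must give at least one frame")
  time <- (0:n) / rate
  tau <- pmin(time / duration, 1)
  s <- min_jerk_profile(tau)
  pos <- outer(rep(1, n + 1L), p0) + outer(s, p1 - p0)
  trajectory_series(time, pos, rate)
}
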