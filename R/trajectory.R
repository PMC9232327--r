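#' Uniformly sampled 3D trajectory
#'
#' Container for a single marker's (here: one hand's) uniformly sampled 3D
#' position time series, the input to all kinematic operations.
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing
#'   and uniform at `1/frame_rate`.
#' @param pos numeric matrix with one row per timestamp and columns
#'   `x`, `y`, `z` (meters). Axis convention: x mediolateral, y
#'   anteroposterior, z vertical, so the XY plane is horizontal, XZ frontal
#'   and YZ sagittal.
#' @param frame_rate sampling rate in Hz.
#'
#' @return An object of class `trajectory_series` with elements `time`,
#'   `pos` and `frame_rate`.
#' @export
trajectory_series <- function(time, pos, frame_rate) {
  pos <- as.matrix(pos)
  if (!is_scalar_number(frame_rate) || frame_rate <= 0) {
    stop_invalid("`frame_rate` must be a positive number")
  }
  if (length(time) < 2L) {
    stop_invalid("a trajectory needs at least 2 samples")
  }
  if (nrow(pos) != length(time) || ncol(pos) != 3L) {
    stop_invalid("`pos` must be a length(time) x 3 matrix")
  }
  dt <- diff(time)
  if (any(dt <= 0) || any(abs(dt - 1 / frame_rate) >= 1e-9)) {
    stop_invalid("timestamps must be uniform at 1/frame_rate (tolerance 1e-9)")
  }
  colnames(pos) <- c("x", "y", "z")
  structure(
    list(time = as.numeric(time), pos = pos, frame_rate = frame_rate),
    class = "trajectory_series"
  )
}

#' @export
print.trajectory_series <- function(x, ...) {
  cat(sprintf(
    "<trajectory_series> %d frames @ %g Hz, %.3f s\n",
    length(x$time), x$frame_rate, x$time[length(x$time)] - x$time[1]
  ))
  invisible(x)
}

n_frames <- function(traj) length(traj$time)

#' Anatomical plane codes
#'
#' The three coordinate planes used for projected track lengths, with their
#' anatomical labels under the package's axis convention.
#'
#' @return Named character vector mapping plane code to anatomical label:
#'   `XY` = horizontal, `XZ` = frontal, `YZ` = sagittal.
#' @export
plane_codes <- function() {
  c(XY = "horizontal", XZ = "frontal", YZ = "sagittal")
}

plane_columns <- function(plane) {
  switch(plane,
    XY = c(1L, 2L),
    XZ = c(1L, 3L),
    YZ = c(2L, 3L),
    stop_invalid("unknown plane code: ", plane, " (expected XY, XZ or YZ)")
  )
}
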