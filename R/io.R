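# CSV interchange: one trajectory file, one EMG file and one MVIC file per
# subject (x combination), plus a JSON cohort manifest. CSV is the canonical
# format; columns follow the documented schemas exactly so files round-trip
# byte-identically under a fixed config.

#' Write a motion trial to CSV
#'
#' Long format: `time_s`, `hand`, `x_m`, `y_m`, `z_m`.
#'
#' @param motion a `motion_trial`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(motion, path) {
  rows <- do.call(rbind, lapply(c("left", "right"), function(hand) {
    tr <- motion[[hand]]
    data.frame(time_s = tr$time, hand = hand,
               x_m = tr$pos[, 1], y_m = tr$pos[, 2], z_m = tr$pos[, 3])
  }))
  write.csv(format_num(rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV into per-hand series
#'
#' @param path CSV written by [write_trajectory_csv()].
#' @param frame_rate capture rate (Hz); inferred from timestamps if `NULL`.
#' @return Named list of [trajectory_series] (`left`, `right`).
#' @export
read_trajectory_csv <- function(path, frame_rate = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time_s", "hand", "x_m", "y_m", "z_m")
  if (!all(needed %in% names(d))) {
    stop_invalid("trajectory CSV must have columns ", paste(needed, collapse = ", "))
  }
  out <- lapply(split(d, d$hand), function(h) {
    fr <- frame_rate %||% round(1 / stats::median(diff(h$time_s)))
    trajectory_series(h$time_s, as.matrix(h[, c("x_m", "y_m", "z_m")]), fr)
  })
  out[c("left", "right")]
}

#' Write an EMG trial to CSV
#'
#' Wide format: `time_s` plus one column per channel (`side_muscle`).
#'
#' @param emg an `emg_trial`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_emg_csv <- function(emg, path) {
  n <- length(emg$channels[[1]])
  d <- data.frame(time_s = (0:(n - 1L)) / emg$rate)
  for (ch in names(emg$channels)) d[[ch]] <- emg$channels[[ch]]
  write.csv(format_num(d), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an EMG CSV
#'
#' @param path CSV written by [write_emg_csv()].
#' @param rate sampling rate (Hz); inferred from timestamps if `NULL`.
#' @return List with `channels` (named list of numeric vectors), `rate`,
#'   `duration_s`.
#' @export
read_emg_csv <- function(path, rate = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(d)) stop_invalid("EMG CSV must have a time_s column")
  chans <- setdiff(names(d), "time_s")
  if (!length(chans)) stop_invalid("EMG CSV has no channel columns")
  if (any(!vapply(d[chans], is.numeric, TRUE)) ||
      any(!is.finite(as.matrix(d[chans])))) {
    stop_invalid("EMG CSV contains non-numeric or non-finite values")
  }
  r <- rate %||% round(1 / stats::median(diff(d$time_s)))
  list(channels = as.list(d[chans]), rate = r,
       duration_s = nrow(d) / r)
}

#' Write MVIC references to CSV
#'
#' Columns: `channel`, `reference_rms`, `reference_meanabs`.
#'
#' @param mvic an `mvic_trial` or its reference data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mvic_csv <- function(mvic, path) {
  refs <- mvic_ref_table(mvic)
  write.csv(format_num(refs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an MVIC reference CSV
#'
#' @param path CSV written by [write_mvic_csv()].
#' @return data.frame with `channel`, `reference_rms`, `reference_meanabs`.
#' @export
read_mvic_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("channel", "reference_rms", "reference_meanabs")
  if (!all(needed %in% names(d))) {
    stop_invalid("MVIC CSV must have columns ", paste(needed, collapse = ", "))
  }
  d
}

# Format numeric columns with full precision but a stable textual form so
# repeated writes are byte-identical across platforms.
format_num <- function(d) {
  for (col in names(d)) {
    if (is.numeric(d[[col]])) {
      d[[col]] <- formatC(d[[col]], format = "g", digits = 17)
    }
  }
  d
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$geometry <- unclass(out$geometry)
  out$amplitude_scale <- as.list(out$amplitude_scale)
  out$braking_sharpness <- as.list(out$braking_sharpness)
  out$muscle_weights <- lapply(out$muscle_weights, as.list)
  out
}

list_to_config <- function(lst) {
  geometry <- do.call(arm_geometry, lst$geometry)
  cohort_config(
    n_group_a = lst$n_group_a, n_group_b = lst$n_group_b, seed = lst$seed,
    frame_rate = lst$frame_rate, emg_rate = lst$emg_rate, tempo = lst$tempo,
    height_mean = lst$height_mean, height_sd = lst$height_sd,
    amplitude_scale = unlist(lst$amplitude_scale),
    subject_amp_sd = lst$subject_amp_sd,
    braking_sharpness = unlist(lst$braking_sharpness),
    muscle_weights = lapply(lst$muscle_weights, unlist),
    side_asymmetry = lst$side_asymmetry,
    coord_noise_sd = lst$coord_noise_sd, emg_noise_sd = lst$emg_noise_sd,
    activation_sd = lst$activation_sd,
    emg_band = unlist(lst$emg_band), mvic_headroom = lst$mvic_headroom,
    mvic_duration_s = lst$mvic_duration_s, mvic_window_s = lst$mvic_window_s,
    prob_right_handed = lst$prob_right_handed, geometry = geometry
  )
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}
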