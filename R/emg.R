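#' Surface-EMG channel series
#'
#' Container for one channel of raw or preprocessed surface EMG.
#'
#' @param values numeric vector of signal amplitudes (mV), finite.
#' @param rate sampling rate in Hz.
#' @param channel optional channel id, conventionally `side_muscle`
#'   (see [emg_channels()]).
#' @return An object of class `emg_series`.
#' @export
emg_series <- function(values, rate, channel = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop_invalid("an EMG series needs at least 1 sample")
  if (any(!is.finite(values))) stop_invalid("EMG values must be finite")
  if (!is_scalar_number(rate) || rate <= 0) stop_invalid("`rate` must be positive")
  structure(list(values = values, rate = rate, channel = channel),
            class = "emg_series")
}

#' The eight EMG channels of the protocol
#'
#' Bilateral biceps brachii, triceps brachii, middle deltoid and latissimus
#' dorsi, keyed `side_muscle`.
#'
#' @return Character vector of the 8 channel ids (left side first).
#' @export
emg_channels <- function() {
  muscles <- c("biceps_brachii", "triceps_brachii", "deltoid_middle",
               "latissimus_dorsi")
  c(paste0("left_", muscles), paste0("right_", muscles))
}

as_values <- function(signal) {
  if (inherits(signal, "emg_series")) signal$values else as.numeric(signal)
}

#' Root-mean-square EMG amplitude
#'
#' `sqrt(mean(x^2))` over a window; the amplitude index of motor-unit
#' recruitment intensity.
#'
#' @param signal an [emg_series] or numeric vector (a window of one).
#' @return RMS amplitude in the signal's units (mV).
#' @export
emg_rms <- function(signal) {
  x <- as_values(signal)
  if (length(x) < 1L) stop_invalid("empty window: RMS undefined")
  sqrt(mean(x^2))
}

#' Integrated EMG (iEMG)
#'
#' Numerical time-integral of the rectified signal over a window,
#' `sum(|x_i|) / rate` (left Riemann sum; `method = "trapezoid"` uses the
#' trapezoidal rule, which differs negligibly at 1000 Hz). Indexes total
#' muscle-fiber participation; units mV·s.
#'
#' @param signal an [emg_series], or numeric vector with `rate` given.
#' @param rate sampling rate in Hz (taken from the series if omitted).
#' @param method `"riemann"` (default) or `"trapezoid"`.
#' @return Integrated rectified amplitude in mV·s.
#' @export
emg_iemg <- function(signal, rate = NULL, method = c("riemann", "trapezoid")) {
  method <- match.arg(method)
  if (inherits(signal, "emg_series")) rate <- rate %||% signal$rate
  if (is.null(rate)) stop_invalid("`rate` is required for a bare numeric signal")
  x <- abs(as_values(signal))
  if (length(x) < 2L) stop_invalid("iEMG needs at least 2 samples")
  if (method == "riemann") {
    sum(x) / rate
  } else {
    (sum(x) - (x[1] + x[length(x)]) / 2) / rate
  }
}

#' Standardize an EMG metric to its MVIC reference
#'
#' Expresses a task value as a percentage of the maximum voluntary
#' isometric contraction (MVIC) reference of the same kind, the 100%
#' anchor. Values above 100% are permitted.
#'
#' @param value task-window metric (mV or mV·s).
#' @param reference MVIC reference of the same kind (> 0).
#' @return Percentage `100 * value / reference`.
#' @export
emg_standardize <- function(value, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop_invalid("MVIC `reference` must be positive")
  }
  100 * value / reference
}

#' Band-pass preprocessing of raw EMG
#'
#' Optional zero-phase Butterworth band-pass (default 20–450 Hz, the
#' conventional sEMG bandwidth) followed by mean removal. With
#' `enabled = FALSE` the input is returned unchanged.
#'
#' @param raw an [emg_series].
#' @param band length-2 numeric band edges in Hz.
#' @param enabled logical; `FALSE` gives the identity.
#' @param order Butterworth order per pass.
#' @return A preprocessed [emg_series].
#' @export
emg_preprocess <- function(raw, band = c(20, 450), enabled = TRUE, order = 4) {
  if (!enabled) return(raw)
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1]) {
    stop_invalid("`band` must be increasing positive edges (Hz)")
  }
  if (raw$rate < 2 * band[2]) {
    stop_invalid("sample rate must be at least twice the upper band edge")
  }
  bf <- signal::butter(order, band / (raw$rate / 2), type = "pass")
  x <- signal::filtfilt(bf, raw$values)
  emg_series(x - mean(x), raw$rate, raw$channel)
}

#' MVIC reference statistics from a contraction trial
#'
#' Scans the MVIC recording with a sliding window (default 1 s) and takes
#' the window with the highest RMS as the standardization reference. The
#' mean rectified amplitude over that same window is also returned, as the
#' reference for duration-matched iEMG standardization.
#'
#' @param signal an [emg_series] of the MVIC trial.
#' @param window_s sliding window length in seconds.
#' @return List with `rms` (reference RMS, mV), `mean_abs` (mean rectified
#'   amplitude over the best window, mV) and `window_start_s`.
#' @export
mvic_reference <- function(signal, window_s = 1) {
  x <- as_values(signal)
  rate <- signal$rate
  w <- min(length(x), max(2L, round(window_s * rate)))
  cs2 <- cumsum(c(0, x^2))
  csa <- cumsum(c(0, abs(x)))
  starts <- 1:(length(x) - w + 1L)
  ms <- (cs2[starts + w] - cs2[starts]) / w
  best <- which.max(ms)
  list(
    rms = sqrt(ms[best]),
    mean_abs = (csa[best + w] - csa[best]) / w,
    window_start_s = (best - 1L) / rate
  )
}

# Map beat boundary times (s) to 1-based sample index windows at the EMG
# rate by nearest-sample rounding; windows partition the covered span.
beat_sample_windows <- function(boundaries_s, rate, n_samples) {
  edges <- round(boundaries_s * rate)
  if (any(edges < 0) || any(edges > n_samples + 1)) {
    stop_invalid("beat boundary outside the EMG trial")
  }
  edges[length(edges)] <- min(edges[length(edges)], n_samples)
  lapply(seq_len(length(edges) - 1L), function(k) {
    (edges[k] + 1L):edges[k + 1L]
  })
}

#' Per-beat and whole-trial standardized EMG metrics
#'
#' For every channel of an EMG trial, computes RMS and iEMG over each beat
#' window and over the whole trial, standardized to the subject's MVIC
#' references: RMS as a percentage of the reference RMS, iEMG as a
#' percentage of the MVIC iEMG accumulated over a window of equal duration
#' (`mean_abs * duration`).
#'
#' @param trial an EMG trial: list with `channels` (named list or matrix of
#'   per-channel values), `rate` (Hz). [generate_emg_trial()] produces one.
#' @param boundaries_s beat boundary times in seconds (length
#'   `n_beats + 1`, increasing, within the trial).
#' @param mvic MVIC references: data.frame with columns `channel`,
#'   `reference_rms`, `reference_meanabs` (as produced by
#'   [generate_mvic()]), or a named list of [mvic_reference()] results.
#' @return A data.frame with one row per channel x window (beat index as
#'   character, plus `"trial"`): `channel`, `window`, `rms_mv`,
#'   `iemg_mvs`, `rms_pct`, `iemg_pct`.
#' @export
per_beat_emg <- function(trial, boundaries_s, mvic) {
  rate <- trial$rate
  ch_values <- trial$channels
  if (is.matrix(ch_values)) {
    ch_values <- stats::setNames(
      lapply(seq_len(ncol(ch_values)), function(j) ch_values[, j]),
      colnames(ch_values)
    )
  }
  refs <- mvic_ref_table(mvic)
  n <- length(ch_values[[1]])
  if (any(diff(boundaries_s) <= 0)) stop_invalid("beat boundaries must increase")
  windows <- beat_sample_windows(boundaries_s, rate, n)
  names(windows) <- as.character(seq_along(windows))
  windows$trial <- seq_len(n)
  rows <- list()
  for (ch in names(ch_values)) {
    x <- ch_values[[ch]]
    ref_rms <- refs$reference_rms[refs$channel == ch]
    ref_ma <- refs$reference_meanabs[refs$channel == ch]
    if (length(ref_rms) != 1L) stop_invalid("missing MVIC reference for channel ", ch)
    for (w in names(windows)) {
      idx <- windows[[w]]
      rms <- emg_rms(x[idx])
      iemg <- sum(abs(x[idx])) / rate
      dur <- length(idx) / rate
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, window = w, rms_mv = rms, iemg_mvs = iemg,
        rms_pct = emg_standardize(rms, ref_rms),
        iemg_pct = emg_standardize(iemg, ref_ma * dur),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

mvic_ref_table <- function(mvic) {
  if (is.data.frame(mvic)) return(mvic)
  if (is.data.frame(mvic$reference)) return(mvic$reference)
  data.frame(
    channel = names(mvic),
    reference_rms = vapply(mvic, `[[`, 0, "rms"),
    reference_meanabs = vapply(mvic, `[[`, 0, "mean_abs"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
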