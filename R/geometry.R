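#' Canonical arm geometry for the synthetic cohort
#'
#' Defines the via-point geometry of the test movements in a body-fixed frame
#' centered between the shoulders: x mediolateral (right positive),
#' y anteroposterior (forward positive), z vertical. Hand positions are
#' placed one arm length from the shoulder in the direction each named
#' action ends at. All distances in meters, for a reference stature of
#' `reference_height`; per-subject geometry is scaled by
#' `height / reference_height`.
#'
#' @param arm_length shoulder-to-hand distance for an extended arm (m).
#' @param half_shoulder half the biacromial shoulder width (m).
#' @param chest_depth forward (y) reach of the crossed hands in the
#'   chest-cross connecting action (m).
#' @param chest_overlap how far each hand crosses the midline in the
#'   chest-cross action (m).
#' @param down_forward_tilt forward tilt, as a y:z direction component, of
#'   the hanging-arm "down" position (dimensionless).
#' @param side_elevation_deg elevation of the side-up / side-down lift
#'   endpoints above/below horizontal (degrees).
#' @param reference_height stature the geometry is calibrated to (m).
#' @return An object of class `arm_geometry` (a named list of parameters).
#' @export
arm_geometry <- function(arm_length = 0.6,
                         half_shoulder = 0.18,
                         chest_depth = 0.55,
                         chest_overlap = 0.15,
                         down_forward_tilt = 0.15,
                         side_elevation_deg = 45,
                         reference_height = 1.77) {
  stopifnot(arm_length > 0, half_shoulder >= 0, reference_height > 0)
  structure(
    list(
      arm_length = arm_length, half_shoulder = half_shoulder,
      chest_depth = chest_depth, chest_overlap = chest_overlap,
      down_forward_tilt = down_forward_tilt,
      side_elevation_deg = side_elevation_deg,
      reference_height = reference_height
    ),
    class = "arm_geometry"
  )
}

# End positions of every named action for one hand ("left"/"right").
hand_via_points <- function(geometry, hand) {
  sx <- if (hand == "right") 1 else -1
  r <- geometry$arm_length
  shoulder <- c(sx * geometry$half_shoulder, 0, 0)
  down_dir <- c(0, geometry$down_forward_tilt, -sqrt(1 - geometry$down_forward_tilt^2))
  elev <- geometry$side_elevation_deg * pi / 180
  down <- shoulder + r * down_dir
  list(
    down       = down,
    down_lift  = down,
    front_lift = shoulder + c(0, r, 0),
    up_lift    = shoulder + c(0, 0, r),
    side_lift  = shoulder + c(sx * r, 0, 0),
    chest_cross = c(-sx * geometry$chest_overlap, geometry$chest_depth, 0),
    side_up_lift   = shoulder + r * c(sx * cos(elev), 0, sin(elev)),
    side_down_lift = shoulder + r * c(sx * cos(elev), 0, -sin(elev))
  )
}

#' Build the script of a test-movement combination
#'
#' The two fixed combinations of the protocol, as chained beat-wise
#' via-points per hand. Combination 1 is the symmetric 8-beat sequence
#' front lift, up lift, side lift, down lift, side lift, up lift, front
#' lift, down lift (so beats 1 and 7 are front lifts, 2 and 6 up lifts,
#' 3 and 5 side lifts, 4 and 8 down lifts). Combination 2 is the 4-beat
#' sequence chest cross, side-up lift, chest cross, side-down lift, with
#' the chest cross as the connecting action on beats 1 and 3 and the
#' side-up / side-down endpoints at +/-45 degrees elevation. Both start
#' from the hanging-arm "down" position. Both hands move mirror-symmetric
#' and simultaneously.
#'
#' @param combo_id 1 or 2.
#' @param tempo metronome tempo in beats per minute (> 0).
#' @param geometry an [arm_geometry()].
#' @return An object of class `combination_script`: list with `combo_id`,
#'   `tempo`, `n_beats` and `beats`, where each beat holds `beat_index`,
#'   `action_name` and start/end positions per hand. Consecutive beats
#'   chain: the end of beat k is the start of beat k+1.
#' @export
build_combination_script <- function(combo_id, tempo = 120,
                                     geometry = arm_geometry()) {
  if (!is_scalar_number(combo_id) || !combo_id %in% c(1, 2)) {
    stop_invalid("`combo_id` must be 1 or 2")
  }
  if (!is_scalar_number(tempo) || tempo <= 0) {
    stop_invalid("`tempo` must be a positive number")
  }
  actions <- if (combo_id == 1) {
    c("front_lift", "up_lift", "side_lift", "down_lift",
      "side_lift", "up_lift", "front_lift", "down_lift")
  } else {
    c("chest_cross", "side_up_lift", "chest_cross", "side_down_lift")
  }
  via <- list(
    left = hand_via_points(geometry, "left"),
    right = hand_via_points(geometry, "right")
  )
  keys <- c("down", actions)
  beats <- lapply(seq_along(actions), function(k) {
    list(
      beat_index = k,
      action_name = actions[k],
      left_start = via$left[[keys[k]]], left_end = via$left[[keys[k + 1]]],
      right_start = via$right[[keys[k]]], right_end = via$right[[keys[k + 1]]]
    )
  })
  structure(
    list(combo_id = as.integer(combo_id), tempo = tempo,
         n_beats = length(beats), beats = beats, geometry = geometry),
    class = "combination_script"
  )
}

#' @export
print.combination_script <- function(x, ...) {
  cat(sprintf("<combination_script> combo %d: %d beats @ %g bpm\n",
              x$combo_id, x$n_beats, x$tempo))
  cat(" ", paste(vapply(x$beats, `[[`, "", "action_name"), collapse = ", "), "\n")
  invisible(x)
}
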