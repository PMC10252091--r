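#' Marker trajectory set
#'
#' A light container for synchronized 3D marker trajectories from one trial.
#' Coordinates follow the laboratory convention used throughout the package:
#' x = lateral, y = direction of travel, z = vertical, all in millimetres.
#'
#' @param time Numeric vector of sample times in seconds (uniform).
#' @param coords Named list of n-by-3 numeric matrices (columns x, y, z),
#'   one per marker, all with `length(time)` rows. `NA` marks occluded
#'   samples.
#' @param rate_hz Sampling rate in Hz.
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(time, coords, rate_hz) {
  stopifnot(is.numeric(time), is.list(coords), length(coords) >= 1,
            !is.null(names(coords)), rate_hz > 0)
  for (nm in names(coords)) {
    m <- coords[[nm]]
    if (!is.matrix(m) || ncol(m) != 3 || nrow(m) != length(time))
      stop("marker '", nm, "' must be a ", length(time), "-by-3 matrix")
    colnames(coords[[nm]]) <- c("x", "y", "z")
  }
  structure(list(time = time, coords = coords, rate_hz = rate_hz),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("<marker_set> ", length(x$coords), " markers, ",
      length(x$time), " frames @ ", x$rate_hz, " Hz (",
      sprintf("%.2f", diff(range(x$time))), " s)\n", sep = "")
  cat("  markers:", paste(names(x$coords), collapse = ", "), "\n")
  invisible(x)
}

#' Surface EMG channel
#'
#' @param time Sample times in seconds.
#' @param values Signal in volts.
#' @param rate_hz Sampling rate in Hz.
#' @param muscle Muscle name.
#' @param horse,lead Optional metadata.
#' @return An object of class `emg_channel`.
#' @export
emg_channel <- function(time, values, rate_hz, muscle = NA_character_,
                        horse = NA_character_, lead = NA_character_) {
  stopifnot(length(time) == length(values), rate_hz > 0)
  structure(list(time = time, values = values, rate_hz = rate_hz,
                 muscle = muscle, horse = horse, lead = lead),
            class = "emg_channel")
}

#' @export
print.emg_channel <- function(x, ...) {
  cat("<emg_channel> ", x$muscle, ": ", length(x$values), " samples @ ",
      x$rate_hz, " Hz\n", sep = "")
  invisible(x)
}

#' Joint angle (or angular velocity) series
#'
#' @param joint Joint name.
#' @param values Angles in degrees (or deg/s for a velocity series).
#' @param rate_hz Sampling rate in Hz.
#' @param normalized Logical; `TRUE` once referenced to the static pose.
#' @param unit `"deg"` or `"deg_s"`.
#' @return An object of class `joint_angle_series`.
#' @export
joint_angle_series <- function(joint, values, rate_hz, normalized = FALSE,
                               unit = "deg") {
  stopifnot(is.numeric(values), rate_hz > 0)
  structure(list(joint = joint, values = values, rate_hz = rate_hz,
                 normalized = normalized, unit = unit),
            class = "joint_angle_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
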