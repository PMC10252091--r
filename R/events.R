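#' Detect hoof impact and lift-off events from a hoof wall marker
#'
#' Speed-threshold event detector: the sagittal-plane speed of the (already
#' filtered) lateral hoof wall marker is computed by central differences;
#' swing peaks define cycles, and within each cycle impact is the first
#' sample where speed falls below `speed_frac` of the preceding swing peak
#' and stays below it for at least `min_dur_s`, while lift-off is the first
#' subsequent sample where speed exceeds `speed_frac` of the next swing peak
#' for at least `min_dur_s`.
#'
#' @param markers A filtered [marker_set].
#' @param limb `"fore"` or `"hind"`.
#' @param hoof Hoof wall marker name (default `<limb>_hoof`).
#' @param speed_frac Amplitude threshold as a fraction of the per-cycle peak
#'   speed (default 0.05).
#' @param min_dur_s Persistence required on either side of a crossing, in
#'   seconds (default 0.025).
#' @param min_peak_speed Minimum swing-peak speed in mm/s for a cycle to
#'   count (default 100); a stationary marker therefore yields no events.
#' @return Data frame with columns `limb`, `impact_s`, `liftoff_s`, one row
#'   per complete stance. Empty (with a warning) when no cycles are found.
#' @export
detect_hoof_events <- function(markers, limb = c("fore", "hind"),
                               hoof = NULL, speed_frac = 0.05,
                               min_dur_s = 0.025, min_peak_speed = 100) {
  limb <- match.arg(limb)
  hoof <- hoof %||% paste0(limb, "_hoof")
  if (is.null(markers$coords[[hoof]]))
    stop("hoof marker '", hoof, "' missing from trial")
  m <- markers$coords[[hoof]]
  rate <- markers$rate_hz
  vy <- deriv_central(m[, 2], rate)
  vz <- deriv_central(m[, 3], rate)
  speed <- sqrt(vy^2 + vz^2)
  empty <- data.frame(limb = character(), impact_s = numeric(),
                      liftoff_s = numeric())
  peaks <- find_speed_peaks(speed, min_dist = round(0.3 * rate),
                            min_height = max(min_peak_speed,
                                             0.5 * max(speed)))
  if (length(peaks) < 2) {
    warning("no detectable ", limb, " hoof cycles")
    return(empty)
  }
  persist <- max(1L, round(min_dur_s * rate))
  out <- list()
  for (k in seq_len(length(peaks) - 1)) {
    seg <- peaks[k]:peaks[k + 1]
    thr_dn <- speed_frac * speed[peaks[k]]
    thr_up <- speed_frac * speed[peaks[k + 1]]
    imp <- sustained_crossing(speed[seg] < thr_dn, persist)
    if (is.na(imp)) next
    lift <- sustained_crossing(speed[seg] > thr_up, persist,
                               from = imp + 1L)
    if (is.na(lift)) next
    out[[length(out) + 1]] <- data.frame(
      limb = limb,
      impact_s = cross_time(markers$time, speed, seg[imp], thr_dn),
      liftoff_s = cross_time(markers$time, speed, seg[lift], thr_up))
  }
  if (!length(out)) {
    warning("no complete ", limb, " stances detected")
    return(empty)
  }
  do.call(rbind, out)
}

# local maxima above min_height, separated by at least min_dist samples
find_speed_peaks <- function(x, min_dist, min_height) {
  n <- length(x)
  if (n < 3) return(integer())
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n] &
                  x[2:(n - 1)] >= min_height) + 1L
  if (!length(cand)) return(integer())
  keep <- integer()
  for (i in cand[order(-x[cand])]) {
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

# sub-sample refinement: linear interpolation of the threshold crossing
# between sample i-1 and the first sample i satisfying the condition
cross_time <- function(time, speed, i, thr) {
  if (i <= 1 || speed[i] == speed[i - 1]) return(time[i])
  frac <- (thr - speed[i - 1]) / (speed[i] - speed[i - 1])
  if (!is.finite(frac) || frac < 0 || frac > 1) return(time[i])
  time[i - 1] + frac * (time[i] - time[i - 1])
}

# first index (at or after `from`) where `cond` holds for >= persist samples
sustained_crossing <- function(cond, persist, from = 1L) {
  cond[seq_len(min(from - 1L, length(cond)))] <- FALSE
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= persist)
  if (!length(hit)) return(NA_integer_)
  starts[hit[1]]
}

#' Segment canter strides from successive hind-hoof impacts
#'
#' Strides run from one right-hind impact to the next, irrespective of
#' whether the hind limb functions as leading (LdH) or trailing (TrH) hind.
#' The recorded (right) limbs are leading in right-lead canter and trailing
#' in left-lead canter. Strides whose window lacks a complete forelimb
#' stance are dropped and counted in the `"dropped"` attribute.
#'
#' @param hind_events,fore_events Event tables from [detect_hoof_events()].
#' @param lead `"left"` or `"right"` canter lead.
#' @param horse Horse identifier.
#' @return Data frame (class `stride_set`), one row per stride, with window
#'   times, stance times and durations, lead and limb-role labels.
#' @export
segment_strides <- function(hind_events, fore_events,
                            lead = c("left", "right"), horse = NA_character_) {
  lead <- match.arg(lead)
  if (nrow(hind_events) < 2)
    stop("need at least 2 hind impacts to segment strides")
  role_fore <- if (lead == "right") "LdF" else "TrF"
  role_hind <- if (lead == "right") "LdH" else "TrH"
  imp <- sort(hind_events$impact_s)
  out <- list(); dropped <- 0L
  for (k in seq_len(length(imp) - 1)) {
    t0 <- imp[k]; t1 <- imp[k + 1]
    hrow <- hind_events[abs(hind_events$impact_s - t0) < 1e-9, ][1, ]
    f <- fore_events[fore_events$impact_s >= t0 & fore_events$impact_s < t1, ]
    f <- f[f$liftoff_s <= t1, ]
    if (nrow(f) < 1) { dropped <- dropped + 1L; next }
    f <- f[1, ]
    out[[length(out) + 1]] <- data.frame(
      horse = horse, lead = lead, stride = NA_integer_,
      start_s = t0, end_s = t1, stride_duration_s = t1 - t0,
      hind_impact_s = t0, hind_liftoff_s = hrow$liftoff_s,
      fore_impact_s = f$impact_s, fore_liftoff_s = f$liftoff_s,
      hind_stance_s = hrow$liftoff_s - t0,
      fore_stance_s = f$liftoff_s - f$impact_s,
      role_fore = role_fore, role_hind = role_hind)
  }
  if (!length(out)) stop("no stride with a complete forelimb stance")
  strides <- do.call(rbind, out)
  strides$stride <- seq_len(nrow(strides))
  attr(strides, "dropped") <- dropped
  class(strides) <- c("stride_set", class(strides))
  strides
}

#' Per-stride spatiotemporal variables
#'
#' Adds stride velocity to a stride table: the mean first derivative of the
#' tubera sacrale marker's y-coordinate (direction of travel) over each
#' stride window, converted from mm/s to m/s.
#'
#' @param strides A stride table from [segment_strides()].
#' @param markers The trial's [marker_set] (filtered).
#' @param trunk Trunk marker name (default `"tubera_sacrale"`).
#' @return The stride table with a `stride_velocity_mps` column.
#' @export
spatiotemporal <- function(strides, markers, trunk = "tubera_sacrale") {
  if (is.null(markers$coords[[trunk]]))
    stop("trunk marker '", trunk, "' missing from trial")
  vy <- deriv_central(markers$coords[[trunk]][, 2], markers$rate_hz)
  strides$stride_velocity_mps <- vapply(seq_len(nrow(strides)), function(k) {
    w <- markers$time >= strides$start_s[k] & markers$time < strides$end_s[k]
    mean(vy[w]) / 1000
  }, numeric(1))
  strides
}
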