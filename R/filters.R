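#' Zero-phase Butterworth filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' so there is no phase lag; the effective magnitude response is squared
#' (an 8th-order roll-off). Zero lag matters here because event timings and
#' angle/EMG waveforms are compared on a common stride clock.
#'
#' @param x Numeric vector, uniformly sampled.
#' @param cutoff_hz Cut-off frequency in Hz (must be below Nyquist).
#' @param rate_hz Sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @param order Filter order before the forward-backward pass (default 4).
#' @return Filtered numeric vector, same length as `x`.
#' @export
butter_zero_phase <- function(x, cutoff_hz, rate_hz, type = c("low", "high"),
                              order = 4) {
  type <- match.arg(type)
  ny <- rate_hz / 2
  if (cutoff_hz <= 0 || cutoff_hz >= ny)
    stop("cutoff_hz must lie in (0, Nyquist = ", ny, " Hz)")
  if (anyNA(x)) stop("cannot filter a series containing missing samples")
  bf <- signal::butter(order, cutoff_hz / ny, type = type)
  n <- length(x)
  # endpoint-matched line removal + odd reflection padding suppress the
  # start/end transients of the forward-backward pass on trended signals
  tt <- seq_len(n)
  slope <- if (n > 1) (x[n] - x[1]) / (n - 1) else 0
  line <- x[1] + slope * (tt - 1)
  x0 <- x - line
  pad <- min(n - 1, ceiling(3 * rate_hz / cutoff_hz))
  xp <- c(2 * x0[1] - x0[(pad + 1):2], x0, 2 * x0[n] - x0[(n - 1):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, xp))[(pad + 1):(pad + n)]
  if (type == "low") y + line else y
}

#' Fill short marker occlusions by cubic-spline interpolation
#'
#' Gaps of at most `max_gap` consecutive missing frames are filled with a
#' cubic spline through the observed samples; longer gaps (and gaps touching
#' the trial boundary) are left missing and reported, so a trial with
#' unfilled samples inside an analysed window can be rejected downstream.
#'
#' @param markers A [marker_set].
#' @param max_gap Maximum gap length, in frames, that is filled (default 10).
#' @return The `marker_set` with short gaps filled; attribute `"gap_report"`
#'   is a data frame of all gaps (marker, coordinate, start frame, length,
#'   filled).
#' @export
interpolate_gaps <- function(markers, max_gap = 10) {
  stopifnot(inherits(markers, "marker_set"), max_gap >= 0)
  report <- list()
  n <- length(markers$time)
  idx <- seq_len(n)
  for (nm in names(markers$coords)) {
    for (j in 1:3) {
      v <- markers$coords[[nm]][, j]
      miss <- is.na(v)
      if (!any(miss)) next
      r <- rle(miss)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      obs <- which(!miss)
      for (k in which(r$values)) {
        interior <- starts[k] > 1 && ends[k] < n
        fill <- interior && r$lengths[k] <= max_gap
        if (fill) {
          gap <- starts[k]:ends[k]
          v[gap] <- stats::spline(x = idx[obs], y = v[obs], xout = gap,
                                  method = "fmm")$y
        }
        report[[length(report) + 1]] <- data.frame(
          marker = nm, coord = c("x", "y", "z")[j],
          start = starts[k], length = r$lengths[k], filled = fill)
      }
      markers$coords[[nm]][, j] <- v
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(marker = character(), coord = character(),
               start = integer(), length = integer(), filled = logical())
  attr(markers, "gap_report") <- report
  markers
}

#' Low-pass filter marker trajectories
#'
#' Zero-phase 4th-order Butterworth low-pass applied to every coordinate of
#' every marker. The 12 Hz default is the conventional cut-off for equine
#' over-ground kinematics.
#'
#' @param markers A [marker_set] with no missing samples.
#' @param cutoff_hz Cut-off frequency in Hz (default 12).
#' @return Filtered `marker_set`.
#' @export
lowpass_kinematics <- function(markers, cutoff_hz = 12) {
  stopifnot(inherits(markers, "marker_set"))
  for (nm in names(markers$coords)) {
    m <- markers$coords[[nm]]
    if (anyNA(m))
      stop("marker '", nm, "' has missing samples; interpolate or drop the trial")
    for (j in 1:3)
      m[, j] <- butter_zero_phase(m[, j], cutoff_hz, markers$rate_hz, "low")
    markers$coords[[nm]] <- m
  }
  markers
}
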