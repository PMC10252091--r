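#' Pre-process a raw sEMG channel
#'
#' DC-offset removal (mean subtraction), zero-phase 4th-order Butterworth
#' high-pass at `cutoff_hz` (default 40 Hz, suppressing movement artefact),
#' then full-wave rectification.
#'
#' @param channel An [emg_channel] (volts).
#' @param cutoff_hz High-pass cut-off in Hz (default 40).
#' @return The channel with rectified values and `rectified = TRUE`.
#' @export
preprocess_emg <- function(channel, cutoff_hz = 40) {
  stopifnot(inherits(channel, "emg_channel"))
  if (channel$rate_hz < 2 * 450)
    stop("sEMG sampling rate ", channel$rate_hz,
         " Hz is below 900 Hz; signal band up to 450 Hz would alias")
  x <- channel$values - mean(channel$values)
  x <- butter_zero_phase(x, cutoff_hz, channel$rate_hz, "high")
  channel$values <- abs(x)
  channel$rectified <- TRUE
  channel
}

#' Linear envelope of a rectified sEMG signal
#'
#' Zero-phase 4th-order Butterworth low-pass of the rectified signal. The
#' 25 Hz cut-off gives the continuous envelope used for waveform analysis;
#' the 10 Hz cut-off gives the smoother envelope used for peak timing.
#'
#' @param rectified An [emg_channel] after [preprocess_emg()], or a numeric
#'   vector (then `rate_hz` must be given).
#' @param cutoff_hz Low-pass cut-off in Hz (default 25).
#' @param rate_hz Sampling rate, required when `rectified` is a bare vector.
#' @return Same type as the input, with enveloped values.
#' @export
emg_envelope <- function(rectified, cutoff_hz = 25, rate_hz = NULL) {
  if (inherits(rectified, "emg_channel")) {
    rectified$values <- butter_zero_phase(rectified$values, cutoff_hz,
                                          rectified$rate_hz, "low")
    rectified$envelope_hz <- cutoff_hz
    return(rectified)
  }
  butter_zero_phase(rectified, cutoff_hz, rate_hz, "low")
}

#' Average rectified value over one stride
#'
#' @param rectified Rectified sEMG values (volts).
#' @param time Sample times (seconds) matching `rectified`.
#' @param window Stride window `c(start_s, end_s)`.
#' @return Mean of the rectified samples with `start <= t < end`.
#' @export
stride_arv <- function(rectified, time, window) {
  w <- time >= window[1] & time < window[2]
  if (!any(w)) stop("empty stride window [", window[1], ", ", window[2], ")")
  mean(rectified[w])
}

#' Flag outlying per-stride values by Tukey fences
#'
#' Values outside `[Q1 - k IQR, Q3 + k IQR]` (default k = 1.5) are flagged.
#' Applied per horse and muscle to per-stride ARVs and per-stride peak
#' amplitudes before normalization, so a spurious spike cannot become the
#' normalization reference.
#'
#' @param x Numeric vector of per-stride values (at least 4).
#' @param k Fence multiplier (default 1.5).
#' @return Logical vector, `TRUE` where the value is an outlier.
#' @export
flag_arv_outliers <- function(x, k = 1.5) {
  if (length(x) < 4)
    stop("need at least 4 strides to screen for outliers")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  x < q[1] - k * iqr | x > q[2] + k * iqr
}

#' Normalize per-stride ARVs to the per-horse/muscle maximum
#'
#' Each surviving (non-outlier) ARV is expressed as a percentage of the
#' maximum surviving ARV across all strides of that horse and muscle, so
#' the maximum stride maps to exactly 100. Outlier strides get `NA`.
#'
#' @param arvs Per-stride ARVs (volts).
#' @param outlier Logical outlier flags (default none).
#' @return Numeric vector in percent.
#' @export
normalize_arv <- function(arvs, outlier = rep(FALSE, length(arvs))) {
  keep <- !outlier & is.finite(arvs)
  mx <- max(arvs[keep])
  if (!is.finite(mx) || mx <= 0) stop("all-zero or empty ARV set")
  out <- ifelse(outlier, NA_real_, arvs * 100 / mx)
  out
}

#' Normalize an envelope to the reference voluntary contraction
#'
#' The RVC is the maximum envelope amplitude across all strides of a horse
#' and muscle, after screening per-stride peak amplitudes with the same
#' Tukey-fence rule as the ARVs; strides whose peak is flagged do not set
#' the RVC but are still normalized (and may exceed 100%).
#'
#' @param envelope Envelope values (volts) for the whole trial/horse.
#' @param time Sample times.
#' @param windows Data frame or matrix of stride windows (columns
#'   `start_s`, `end_s`).
#' @param k Fence multiplier for peak screening (default 1.5).
#' @return List: `pct` (envelope in %RVC), `rvc` (volts), `peak_outlier`
#'   (per-stride logical), `peaks` (per-stride peak volts).
#' @export
rvc_normalize <- function(envelope, time, windows, k = 1.5) {
  windows <- as.data.frame(windows)
  peaks <- vapply(seq_len(nrow(windows)), function(i) {
    w <- time >= windows$start_s[i] & time < windows$end_s[i]
    if (!any(w)) return(NA_real_)
    max(envelope[w])
  }, numeric(1))
  out_fl <- if (sum(is.finite(peaks)) >= 4)
    flag_arv_outliers(peaks, k) else rep(FALSE, length(peaks))
  out_fl[!is.finite(peaks)] <- TRUE
  rvc <- max(peaks[!out_fl], na.rm = TRUE)
  if (!is.finite(rvc) || rvc <= 0) stop("RVC is zero; cannot normalize")
  list(pct = envelope * 100 / rvc, rvc = rvc,
       peak_outlier = out_fl, peaks = peaks)
}

#' Double-threshold sEMG burst detection
#'
#' Candidate active regions are samples of the detection signal above
#' `amp_frac` of that signal's peak amplitude (amplitude threshold). Sub-
#' threshold gaps shorter than the timing threshold (`time_frac` of the
#' cohort mean stride duration) are bridged, then regions shorter than the
#' timing threshold are discarded. Each surviving burst is assigned to the
#' stride containing its midpoint; onset/offset are expressed in % of that
#' stride, onsets wrapping into the previous stride reported modulo 100.
#' The longest burst in each stride is the main burst.
#'
#' By default detection runs on the 25 Hz envelope of the rectified signal;
#' set `use_envelope = FALSE` to threshold the raw rectified signal.
#'
#' @param rectified An [emg_channel] after [preprocess_emg()].
#' @param windows Stride windows (data frame with `start_s`, `end_s`).
#' @param mean_stride_s Mean stride duration across all horses (seconds),
#'   the basis of the timing threshold.
#' @param amp_frac Amplitude threshold fraction (default 0.05).
#' @param time_frac Timing threshold fraction (default 0.05).
#' @param use_envelope Detect on the 25 Hz envelope (default) or on the raw
#'   rectified signal.
#' @param envelope_cutoff_hz Envelope cut-off when `use_envelope` (25).
#' @return Data frame: `stride`, `onset_pct`, `offset_pct`, `duration_pct`,
#'   `onset_s`, `offset_s`, `is_main`. Zero rows when nothing is detected.
#' @export
detect_bursts <- function(rectified, windows, mean_stride_s,
                          amp_frac = 0.05, time_frac = 0.05,
                          use_envelope = TRUE, envelope_cutoff_hz = 25) {
  stopifnot(inherits(rectified, "emg_channel"),
            amp_frac > 0, amp_frac < 1, time_frac > 0, time_frac < 1)
  windows <- as.data.frame(windows)
  sig <- if (use_envelope)
    butter_zero_phase(rectified$values, envelope_cutoff_hz,
                      rectified$rate_hz, "low") else rectified$values
  empty <- data.frame(stride = integer(), onset_pct = numeric(),
                      offset_pct = numeric(), duration_pct = numeric(),
                      onset_s = numeric(), offset_s = numeric(),
                      is_main = logical())
  # the amplitude threshold references the peak of the rectified signal
  # itself; region finding then runs on the smoother detection signal
  pk <- max(rectified$values)
  if (pk <= 0 || max(sig) <= 0) return(empty)
  thr <- amp_frac * pk
  min_len <- max(1L, round(time_frac * mean_stride_s * rectified$rate_hz))
  active <- sig > thr
  # bridge sub-threshold gaps shorter than the timing threshold
  r <- rle(active)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i] && i > 1 && i < length(r$values) &&
        r$lengths[i] < min_len)
      active[starts[i]:ends[i]] <- TRUE
  }
  # minimum-duration rule
  r <- rle(active)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  on_i <- starts[r$values & r$lengths >= min_len]
  off_i <- ends[r$values & r$lengths >= min_len]
  if (!length(on_i)) return(empty)
  tt <- rectified$time
  out <- list()
  for (b in seq_along(on_i)) {
    t_on <- tt[on_i[b]]; t_off <- tt[off_i[b]]
    mid <- (t_on + t_off) / 2
    s <- which(windows$start_s <= mid & mid < windows$end_s)
    if (!length(s)) next
    s <- s[1]
    dur <- windows$end_s[s] - windows$start_s[s]
    onset_pct <- ((t_on - windows$start_s[s]) / dur * 100) %% 100
    offset_pct <- (t_off - windows$start_s[s]) / dur * 100
    out[[length(out) + 1]] <- data.frame(
      stride = s, onset_pct = onset_pct, offset_pct = offset_pct,
      duration_pct = (t_off - t_on) / dur * 100,
      onset_s = t_on, offset_s = t_off, is_main = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  for (s in unique(res$stride)) {
    i <- which(res$stride == s)
    res$is_main[i[which.max(res$duration_pct[i])]] <- TRUE
  }
  res
}

#' Timing of peak amplitude within a stride
#'
#' Argmax of the 10 Hz envelope inside the stride window, as % of the
#' stride; ties resolve to the earliest sample (a constant envelope gives
#' 0%).
#'
#' @param envelope10 Envelope values (10 Hz cut-off).
#' @param time Sample times.
#' @param window Stride window `c(start_s, end_s)`.
#' @return Peak position in % stride.
#' @export
peak_timing <- function(envelope10, time, window) {
  w <- which(time >= window[1] & time < window[2])
  if (!length(w)) stop("empty stride window")
  i <- w[which.max(envelope10[w])]
  (time[i] - window[1]) / (window[2] - window[1]) * 100
}

#' Wrap stride-boundary-straddling activity onsets
#'
#' When a muscle's main-burst onsets straddle the stride boundary (some
#' above `high`, some below `low`), 100 is added to the onsets below `low`
#' so all onsets lie on one continuous scale (an onset of 1.8% in such a
#' muscle becomes 101.8%).
#'
#' @param onsets Main-burst onsets in % stride, one muscle.
#' @param low,high Straddle limits in % stride (defaults 20 and 80).
#' @return Adjusted onsets.
#' @export
wrap_onsets <- function(onsets, low = 20, high = 80) {
  if (any(onsets > high, na.rm = TRUE) && any(onsets < low, na.rm = TRUE))
    onsets[!is.na(onsets) & onsets < low] <-
      onsets[!is.na(onsets) & onsets < low] + 100
  onsets
}
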