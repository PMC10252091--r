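#' Specification of a synthetic canter cohort
#'
#' Defines the study conditions the generator emulates: ridden canter at
#' ~4.4 m/s with ~0.59 s strides, trailing-fore stance 0.29 s, leading-fore
#' stance 0.27 s, hind stance 0.32 s, the three-beat footfall order TrH,
#' LdH-TrF, LdF with the leading-hind impact placed at 55.5% of the
#' trailing-hind stance, kinematics at 232 Hz and sEMG at 2088 Hz.
#'
#' Leading-vs-trailing differences in discrete kinematic variables are
#' injected through `effect_sizes` (leading = trailing + delta); sEMG
#' asymmetry between limb roles lives in `burst_specs`. Setting every entry
#' of `effect_sizes` to zero and using symmetric burst specs yields a null
#' cohort for error-rate studies.
#'
#' @param n_horses Number of horses (default 10).
#' @param strides_per_lead Strides recorded per horse and canter lead
#'   (default 7, giving a cohort on the scale of ~65 strides per lead).
#' @param stride_duration_s Mean stride duration in seconds (0.59).
#' @param fore_stance_s,hind_stance_s Trailing-limb stance durations in
#'   seconds (0.29, 0.32).
#' @param stride_velocity_mps Mean stride velocity in m/s (4.41).
#' @param advanced_placement_ratio TrH-to-LdH advanced placement as a
#'   fraction of TrH stance duration (0.555).
#' @param timing_cv Stride-to-stride multiplicative timing jitter,
#'   coefficient of variation (0.03).
#' @param limb_segment_lengths_mm Named segment lengths in mm.
#' @param burst_specs Per-muscle, per-limb-role burst definitions, see
#'   [default_burst_specs()].
#' @param emg_snr_db Within-burst to outside-burst RMS ratio in dB (20).
#' @param emg_amplitude_v Baseline burst plateau RMS in volts (1e-3).
#' @param emg_dc_offset_v DC offset added to raw sEMG in volts (5e-4).
#' @param kin_rate_hz,emg_rate_hz Sampling rates (232, 2088).
#' @param effect_sizes Named list of leading-minus-trailing deltas for
#'   discrete variables (`fore_stance_s`, `hind_stance_s`,
#'   `stride_duration_s`, `stride_velocity_mps`, `joint_angle_deg`).
#' @param effect_window Stride window (in % stride) over which
#'   `joint_angle_deg` is applied (default `c(40, 60)`).
#' @param seed Integer seed; all generation is deterministic given the spec.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_horses = 10,
                        strides_per_lead = 7,
                        stride_duration_s = 0.59,
                        fore_stance_s = 0.29,
                        hind_stance_s = 0.32,
                        stride_velocity_mps = 4.41,
                        advanced_placement_ratio = 0.555,
                        timing_cv = 0.03,
                        limb_segment_lengths_mm = default_segment_lengths(),
                        burst_specs = default_burst_specs(),
                        emg_snr_db = 20,
                        emg_amplitude_v = 1e-3,
                        emg_dc_offset_v = 5e-4,
                        kin_rate_hz = 232,
                        emg_rate_hz = 2088,
                        effect_sizes = list(fore_stance_s = -0.02,
                                            hind_stance_s = 0,
                                            stride_duration_s = 0,
                                            stride_velocity_mps = 0.01,
                                            joint_angle_deg = 0),
                        effect_window = c(40, 60),
                        seed = 1L) {
  spec <- list(n_horses = n_horses, strides_per_lead = strides_per_lead,
               stride_duration_s = stride_duration_s,
               fore_stance_s = fore_stance_s, hind_stance_s = hind_stance_s,
               stride_velocity_mps = stride_velocity_mps,
               advanced_placement_ratio = advanced_placement_ratio,
               timing_cv = timing_cv,
               limb_segment_lengths_mm = limb_segment_lengths_mm,
               burst_specs = burst_specs,
               emg_snr_db = emg_snr_db,
               emg_amplitude_v = emg_amplitude_v,
               emg_dc_offset_v = emg_dc_offset_v,
               kin_rate_hz = kin_rate_hz, emg_rate_hz = emg_rate_hz,
               effect_sizes = effect_sizes, effect_window = effect_window,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    stopifnot(n_horses >= 1, strides_per_lead >= 1,
              stride_duration_s > 0, fore_stance_s > 0, hind_stance_s > 0,
              timing_cv >= 0, emg_rate_hz >= 2 * 450, kin_rate_hz > 2 * 12)
    ld_fore <- fore_stance_s + (effect_sizes$fore_stance_s %||% 0)
    ld_hind <- hind_stance_s + (effect_sizes$hind_stance_s %||% 0)
    if (any(c(fore_stance_s, ld_fore, hind_stance_s, ld_hind) >=
              stride_duration_s))
      stop("stance duration must be shorter than the stride")
    for (st in c(fore_stance_s, ld_fore)) {
      if (advanced_placement_ratio * max(hind_stance_s, ld_hind) + st >=
            stride_duration_s)
        stop("footfall timing inconsistent: forelimb stance would overrun ",
             "the next hind impact")
    }
    b <- burst_specs
    stopifnot(all(b$onset_pct >= 0), all(b$onset_pct < 200),
              all(b$offset_pct >= 0), all(b$offset_pct < 200),
              all(b$onset_pct != b$offset_pct), all(b$amp_scale >= 0))
  })
  invisible(spec)
}

#' Default limb segment lengths (mm)
#' @return Named numeric vector, one length per model segment.
#' @export
default_segment_lengths <- function() {
  c(scapula = 250, humerus = 300, radius = 350, metacarpus = 250,
    fore_digit = 120, pelvis = 250, femur = 400, tibia = 400,
    metatarsus = 300, hind_digit = 120)
}

#' Default per-muscle burst specifications
#'
#' One row per muscle and limb role. Onsets use the continuous stride
#' scale: values above 100 denote onsets shortly after the hind impact of a
#' burst whose bulk led to wrap-around reporting; an onset numerically
#' greater than its offset denotes a burst beginning before the stride
#' boundary. Values approximate published canter activation timing for the
#' four muscles.
#'
#' @return Data frame: `muscle`, `group` (fore/hind cycle), `role`,
#'   `onset_pct`, `offset_pct`, `amp_scale`.
#' @export
default_burst_specs <- function() {
  data.frame(
    muscle = rep(c("triceps", "splenius", "gluteal", "biceps"), each = 2),
    group = rep(c("fore", "fore", "hind", "hind"), each = 2),
    role = rep(c("trailing", "leading"), 4),
    onset_pct = c(102, 109, 43, 104, 84, 88, 93.5, 94),
    offset_pct = c(57, 57, 81, 61, 33, 34, 32, 36),
    amp_scale = c(1.0, 0.95, 1.0, 0.9, 1.0, 0.85, 0.8, 1.0),
    stringsAsFactors = FALSE)
}

#' Symmetric (null) burst specifications
#'
#' Trailing-limb burst timing and amplitude copied onto the leading role, so
#' limb-role comparisons of sEMG variables are null; used together with
#' all-zero `effect_sizes` for error-rate studies.
#' @return Data frame in the [default_burst_specs()] layout.
#' @export
null_burst_specs <- function() {
  b <- default_burst_specs()
  tr <- b[b$role == "trailing", ]
  ld <- tr; ld$role <- "leading"
  out <- rbind(tr, ld)
  out[order(out$muscle, out$role), ]
}

# deterministic sub-seed for a generation stream, kept inside 32-bit range
stream_seed <- function(seed, horse_idx, lead, stream) {
  lead_i <- if (identical(lead, "right")) 1L else 0L
  stream_i <- match(stream, c("horse", "kin", "emg1", "emg2", "emg3", "emg4"))
  (abs(seed) %% 1000003L) * 2011L + horse_idx * 127L + lead_i * 31L +
    stream_i * 7L
}

# per-horse fixed effects (random intercepts, conformation, EMG gain),
# deterministic in (spec$seed, horse index)
horse_effects <- function(spec, horse_idx) {
  set.seed(stream_seed(spec$seed, horse_idx, "left", "horse"))
  base <- joint_curve_basis()
  k <- nrow(base)
  list(stride_duration_s = stats::rnorm(1, 0, 0.010),
       vel_factor = exp(stats::rnorm(1, 0, 0.045)),
       fore_stance_s = stats::rnorm(1, 0, 0.006),
       hind_stance_s = stats::rnorm(1, 0, 0.006),
       curve_amp_scale = exp(stats::rnorm(k, 0, 0.05)),
       curve_phase_shift = stats::rnorm(k, 0, 0.08),
       emg_gain = exp(stats::rnorm(4, 0, 0.15)),
       height_mm = stats::rnorm(1, 0, 30))
}

# Harmonic basis of the true joint-angle curves: static posture plus four
# stride harmonics (max 4 / 0.59 s = 6.8 Hz, inside the 12 Hz passband).
joint_curve_basis <- function() {
  data.frame(
    joint = c("shoulder", "elbow", "carpus", "MCPJ",
              "hip", "stifle", "tarsus", "MTPJ"),
    static = c(-50, -26, 4, 12, -55, 40, -38, 14),
    a1 = c(9, 22, 32, 22, 13, 22, 20, 20),
    a2 = c(4, 9, 13, 9, 5, 9, 8, 8),
    a3 = c(1.5, 3.5, 5, 3.5, 2, 3.5, 3, 3),
    a4 = c(0.5, 1.2, 1.8, 1.2, 0.7, 1.2, 1, 1),
    p1 = c(0.3, 1.1, 2.0, 2.6, 0.8, 1.7, 2.3, 2.9),
    p2 = c(1.0, 1.9, 2.7, 0.2, 1.4, 2.4, 3.0, 0.6),
    p3 = c(1.7, 2.6, 0.4, 1.0, 2.1, 3.1, 0.8, 1.4),
    p4 = c(2.4, 0.2, 1.1, 1.8, 2.8, 0.5, 1.5, 2.2),
    stringsAsFactors = FALSE)
}

# evaluate one joint's true angle (deg) at stride phase phi (cycles)
eval_joint_curve <- function(row, phi, amp_scale = 1, phase_shift = 0,
                             gain = 1) {
  row$static + gain * amp_scale *
    (row$a1 * sin(2 * pi * phi + row$p1 + phase_shift) +
     row$a2 * sin(4 * pi * phi + row$p2 + phase_shift) +
     row$a3 * sin(6 * pi * phi + row$p3 + phase_shift) +
     row$a4 * sin(8 * pi * phi + row$p4 + phase_shift))
}

smoothstep <- function(u) ifelse(u <= 0, 0, ifelse(u >= 1, 1, u^2 * (3 - 2 * u)))
swing_arc <- function(u, h) ifelse(u <= 0 | u >= 1, 0, h * sin(pi * u)^2)

# Normalized swing advance: speed profile v0 + (vp - v0) sin^2(pi u) with
# v0 = a * vp, so the hoof lands (and leaves) with ~10% of its peak swing
# speed and stops abruptly at contact, as real hooves do. Closed-form
# integral, scaled so progress runs 0 -> 1 over the swing.
swing_progress <- function(u, a = 0.1) {
  uu <- pmin(pmax(u, 0), 1)
  raw <- a * uu + (1 - a) * (uu / 2 - sin(2 * pi * uu) / (4 * pi))
  raw * 2 / (1 + a)
}

# hoof wall marker trajectory from impact/liftoff truth
hoof_trajectory <- function(time, impacts, liftoffs, contacts_y, z0 = 30,
                            arc_mm = 60) {
  y <- numeric(length(time)); z <- rep(z0, length(time))
  n <- length(impacts)
  # before first impact: approach from a virtual previous contact
  y[] <- NA
  for (k in seq_len(n)) {
    st <- time >= impacts[k] & time <= liftoffs[k]
    y[st] <- contacts_y[k]
    if (k < n) {
      sw <- time > liftoffs[k] & time < impacts[k + 1]
      u <- (time[sw] - liftoffs[k]) / (impacts[k + 1] - liftoffs[k])
      y[sw] <- contacts_y[k] + (contacts_y[k + 1] - contacts_y[k]) * swing_progress(u)
      z[sw] <- z0 + swing_arc(u, arc_mm)
    }
  }
  # lead-in: virtual stance/swing ending at the first impact
  pre <- time < impacts[1]
  if (any(pre)) {
    T_sw <- if (n > 1) impacts[2] - liftoffs[1] else 0.27
    L <- if (n > 1) contacts_y[2] - contacts_y[1] else 2600
    v_lift <- impacts[1] - T_sw
    u <- (time[pre] - v_lift) / T_sw
    y[pre] <- contacts_y[1] - L + L * swing_progress(u)
    z[pre] <- z0 + swing_arc(u, arc_mm)
  }
  # tail-out: next swing after the last lift-off
  post <- time > liftoffs[n]
  if (any(post)) {
    T_sw <- if (n > 1) impacts[n] - liftoffs[n - 1] else 0.27
    L <- if (n > 1) contacts_y[n] - contacts_y[n - 1] else 2600
    u <- (time[post] - liftoffs[n]) / T_sw
    y[post] <- contacts_y[n] + L * swing_progress(u)
    z[post] <- z0 + swing_arc(u, arc_mm)
  }
  cbind(y = y, z = z)
}

#' Generate one synthetic canter trial's marker trajectories
#'
#' Builds the trial's event timeline (hind impacts segment strides; the
#' same-side fore impact sits at the advanced-placement ratio of the hind
#' stance after each hind impact), drives a planar linkage of the model
#' segments with band-limited true joint-angle curves, translates it
#' forward at the stride velocity, and writes hoof wall markers that are
#' stationary (within jitter) during stance. Out-of-plane (x) coordinates
#' are constant plus jitter.
#'
#' @param spec A [cohort_spec].
#' @param horse Horse index (1-based) or id string `"H03"`.
#' @param lead `"left"` or `"right"`; right limbs are leading in right-lead
#'   canter.
#' @param n_strides Number of complete strides (default
#'   `spec$strides_per_lead`).
#' @return List: `markers` (a [marker_set]), `truth` (event times, true
#'   joint-angle curves, stride table, roles).
#' @export
generate_kinematics <- function(spec, horse, lead = c("left", "right"),
                                n_strides = spec$strides_per_lead) {
  lead <- match.arg(lead)
  hidx <- parse_horse(horse)
  he <- horse_effects(spec, hidx)
  set.seed(stream_seed(spec$seed, hidx, lead, "kin"))
  leading <- lead == "right"
  eff <- function(nm) if (leading) (spec$effect_sizes[[nm]] %||% 0) else 0

  K <- n_strides
  jit <- function(n) exp(stats::rnorm(n, 0, spec$timing_cv))
  T_mean <- spec$stride_duration_s + he$stride_duration_s +
    eff("stride_duration_s")
  Tk <- T_mean * jit(K)
  t1 <- 0.35
  hind_imp <- t1 + c(0, cumsum(Tk))                   # K + 1 impacts
  hs_mean <- spec$hind_stance_s + he$hind_stance_s + eff("hind_stance_s")
  hs <- hs_mean * jit(K + 1)
  hind_lift <- hind_imp + hs
  fs_mean <- spec$fore_stance_s + he$fore_stance_s + eff("fore_stance_s")
  fore_imp <- hind_imp + spec$advanced_placement_ratio * hs +
    stats::rnorm(K + 1, 0, 0.002)
  fore_lift <- fore_imp + fs_mean * jit(K + 1)

  # between-horse and trial-to-trial velocity variation is multiplicative,
  # so a zero-velocity spec stays exactly in place
  v <- (spec$stride_velocity_mps + eff("stride_velocity_mps")) *
    he$vel_factor * exp(stats::rnorm(1, 0, 0.012))
  v_mm <- v * 1000
  # run past the last recorded impact so the detector sees a full final
  # stance flanked by swing peaks on both limbs
  t_end <- hind_imp[K + 1] + 1.15 * spec$stride_duration_s
  time <- seq(0, t_end, by = 1 / spec$kin_rate_hz)
  nfr <- length(time)

  # stride phase (cycles), piecewise linear over the actual stride windows
  phi <- stride_phase(time, hind_imp)

  base <- joint_curve_basis()
  gain <- exp(stats::rnorm(1, 0, 0.03))                # small trial gain
  stride_gain <- exp(stats::rnorm(K + 2, 0, 0.07))     # per-stride curve gain
  # smooth gain profile (knots at stride midpoints) keeps curves band-limited
  g_t <- stats::approx(seq(-1, K) + 0.5, stride_gain, xout = phi,
                       rule = 2)$y
  angles_true <- matrix(NA_real_, nfr, nrow(base),
                        dimnames = list(NULL, base$joint))
  for (i in seq_len(nrow(base))) {
    th <- eval_joint_curve(base[i, ], phi, he$curve_amp_scale[i],
                           he$curve_phase_shift[i], gain)
    osc <- th - base$static[i]
    th <- base$static[i] + osc * g_t
    angles_true[, i] <- th
  }
  # injected leading-vs-trailing waveform offset (smooth-edged window)
  jd <- eff("joint_angle_deg")
  if (jd != 0) {
    pct <- (phi %% 1) * 100
    w <- spec$effect_window
    ramp <- smoothstep((pct - (w[1] - 2)) / 4) * (1 - smoothstep((pct - (w[2] - 2)) / 4))
    angles_true <- angles_true + jd * ramp
  }

  coords <- list()
  noise <- function() matrix(stats::rnorm(nfr * 3, 0, 0.3), nfr, 3)
  # slow stride-to-stride speed fluctuation (~2% CV), integrated to position
  vmod_raw <- butter_zero_phase(stats::rnorm(nfr), 1.5, spec$kin_rate_hz,
                                "low")
  vmod <- 1 + 0.02 * vmod_raw / stats::sd(vmod_raw)
  trunk_y <- cumsum(v_mm * vmod) / spec$kin_rate_hz
  z_ts <- 1550 + he$height_mm + 25 * sin(4 * pi * phi + 1.2)
  coords$tubera_sacrale <- cbind(100, trunk_y - 300 + 12 * sin(2 * pi * phi),
                                 z_ts) + noise()
  z_sc <- 1450 + he$height_mm + 22 * sin(4 * pi * phi + 0.7)
  scap <- cbind(90, trunk_y + 350 + 15 * sin(2 * pi * phi + 0.4), z_sc)
  coords$scapula_prox <- scap + noise()
  z_tc <- 1500 + he$height_mm + 22 * sin(4 * pi * phi + 1.6)
  tcox <- cbind(110, trunk_y - 550 + 15 * sin(2 * pi * phi + 2.0), z_tc)
  coords$tuber_coxae <- tcox + noise()

  model <- horse_limb_model()
  L <- spec$limb_segment_lengths_mm
  fk <- function(base_pt, base_alpha, chain_segments) {
    alpha <- base_alpha
    p <- base_pt
    out <- list()
    for (i in seq_along(chain_segments)) {
      seg <- chain_segments[i]
      if (i > 1) {
        jrow <- model$joints[model$joints$dist_segment == seg, ]
        alpha <- alpha + jrow$sign * angles_true[, jrow$joint] * pi / 180
      }
      p <- p + L[[seg]] * cbind(0, sin(alpha), -cos(alpha))
      nm <- model$segments$dist[model$segments$segment == seg]
      out[[nm]] <- p
    }
    out
  }
  alpha_sc <- 0.45 + 0.10 * sin(2 * pi * phi + 0.9)
  fore_chain <- fk(scap, alpha_sc,
                   c("scapula", "humerus", "radius", "metacarpus", "fore_digit"))
  alpha_pv <- -0.25 + 0.10 * sin(2 * pi * phi + 2.2)
  hind_chain <- fk(tcox, alpha_pv,
                   c("pelvis", "femur", "tibia", "metatarsus", "hind_digit"))
  for (nm in names(fore_chain)) coords[[nm]] <- fore_chain[[nm]] + noise()
  for (nm in names(hind_chain)) coords[[nm]] <- hind_chain[[nm]] + noise()

  # hoof wall markers: authored directly so they are stationary in stance
  hind_contacts <- v_mm * (hind_imp + hs / 2) - 520
  hyz <- hoof_trajectory(time, hind_imp, hind_lift, hind_contacts)
  coords$hind_hoof <- cbind(115, hyz[, "y"], hyz[, "z"]) + noise()
  fore_contacts <- v_mm * (fore_imp + (fore_lift - fore_imp) / 2) + 380
  fyz <- hoof_trajectory(time, fore_imp, fore_lift, fore_contacts)
  coords$fore_hoof <- cbind(95, fyz[, "y"], fyz[, "z"]) + noise()

  markers <- marker_set(time, coords, spec$kin_rate_hz)
  strides <- data.frame(
    stride = seq_len(K),
    start_s = hind_imp[1:K], end_s = hind_imp[2:(K + 1)],
    stride_duration_s = Tk,
    hind_stance_s = hs[1:K],
    fore_impact_s = fore_imp[1:K], fore_liftoff_s = fore_lift[1:K],
    fore_stance_s = fore_lift[1:K] - fore_imp[1:K])
  truth <- list(horse = horse_id(hidx), lead = lead,
                role_fore = if (leading) "LdF" else "TrF",
                role_hind = if (leading) "LdH" else "TrH",
                hind_impacts = hind_imp, hind_liftoffs = hind_lift,
                fore_impacts = fore_imp, fore_liftoffs = fore_lift,
                strides = strides, stride_velocity_mps = v,
                angles_true = angles_true, time = time,
                effects = spec$effect_sizes)
  list(markers = markers, truth = truth)
}

# piecewise stride phase in cycles: phi = k - 1 + frac within stride k,
# extrapolated with the nominal duration outside the recorded strides
stride_phase <- function(time, impacts) {
  K <- length(impacts) - 1
  Tk <- diff(impacts)
  phi <- numeric(length(time))
  pre <- time < impacts[1]
  phi[pre] <- (time[pre] - impacts[1]) / Tk[1]
  post <- time >= impacts[K + 1]
  phi[post] <- K + (time[post] - impacts[K + 1]) / Tk[K]
  for (k in seq_len(K)) {
    w <- time >= impacts[k] & time < impacts[k + 1]
    phi[w] <- k - 1 + (time[w] - impacts[k]) / Tk[k]
  }
  phi
}

parse_horse <- function(horse) {
  if (is.numeric(horse)) return(as.integer(horse))
  as.integer(sub("^H", "", horse))
}
horse_id <- function(i) sprintf("H%02d", i)

#' Generate the static standing trial for one horse
#'
#' Stationary markers at the static joint posture (plus sub-millimetre
#' jitter), used to reference dynamic joint angles to the standing
#' position.
#'
#' @param spec A [cohort_spec].
#' @param horse Horse index or id.
#' @param duration_s Trial length in seconds (default 1).
#' @return A [marker_set].
#' @export
generate_static_trial <- function(spec, horse, duration_s = 1) {
  hidx <- parse_horse(horse)
  he <- horse_effects(spec, hidx)
  set.seed(stream_seed(spec$seed, hidx, "left", "kin") + 499L)
  time <- seq(0, duration_s, by = 1 / spec$kin_rate_hz)
  nfr <- length(time)
  base <- joint_curve_basis()
  model <- horse_limb_model()
  L <- spec$limb_segment_lengths_mm
  coords <- list()
  jt <- function() matrix(stats::rnorm(nfr * 3, 0, 0.05), nfr, 3)
  coords$tubera_sacrale <- cbind(100, rep(-300, nfr),
                                 rep(1550 + he$height_mm, nfr)) + jt()
  scap <- cbind(90, rep(350, nfr), rep(1450 + he$height_mm, nfr))
  coords$scapula_prox <- scap + jt()
  tcox <- cbind(110, rep(-550, nfr), rep(1500 + he$height_mm, nfr))
  coords$tuber_coxae <- tcox + jt()
  static_angles <- matrix(rep(base$static, each = nfr), nfr, nrow(base),
                          dimnames = list(NULL, base$joint))
  fkst <- function(base_pt, alpha0, chain) {
    alpha <- rep(alpha0, nfr); p <- base_pt; out <- list()
    for (i in seq_along(chain)) {
      seg <- chain[i]
      if (i > 1) {
        jrow <- model$joints[model$joints$dist_segment == seg, ]
        alpha <- alpha + jrow$sign * static_angles[, jrow$joint] * pi / 180
      }
      p <- p + L[[seg]] * cbind(0, sin(alpha), -cos(alpha))
      out[[model$segments$dist[model$segments$segment == seg]]] <- p
    }
    out
  }
  fc <- fkst(scap, 0.45, c("scapula", "humerus", "radius", "metacarpus",
                           "fore_digit"))
  hc <- fkst(tcox, -0.25, c("pelvis", "femur", "tibia", "metatarsus",
                            "hind_digit"))
  for (nm in names(fc)) coords[[nm]] <- fc[[nm]] + jt()
  for (nm in names(hc)) coords[[nm]] <- hc[[nm]] + jt()
  coords$fore_hoof <- cbind(95, fc$fore_toe[, 2], rep(30, nfr)) + jt()
  coords$hind_hoof <- cbind(115, hc$hind_toe[, 2], rep(30, nfr)) + jt()
  marker_set(time, coords, spec$kin_rate_hz)
}

#' Generate one synthetic sEMG channel
#'
#' A zero-mean broadband carrier (20-450 Hz band-limited noise,
#' amplitude-normalized) is modulated by per-stride burst envelopes
#' (raised-cosine-edged boxcars whose edge midpoints are the true
#' onset/offset), then additive band-limited noise at the requested SNR and
#' a DC offset are added. True burst windows and true (noise-free) ARVs are
#' recorded.
#'
#' @param spec A [cohort_spec].
#' @param truth Trial truth from [generate_kinematics()].
#' @param muscle One of `"triceps"`, `"splenius"`, `"gluteal"`, `"biceps"`.
#' @param edge_pct Raised-cosine edge width in % stride (default 3).
#' @return List: `channel` (an [emg_channel]), `truth` (per-stride onset /
#'   offset in % stride on the continuous scale, times, clean ARVs).
#' @export
generate_semg <- function(spec, truth, muscle, edge_pct = 3) {
  hidx <- parse_horse(truth$horse)
  midx <- match(muscle, c("triceps", "splenius", "gluteal", "biceps"))
  if (is.na(midx)) stop("unknown muscle '", muscle, "'")
  he <- horse_effects(spec, hidx)
  set.seed(stream_seed(spec$seed, hidx, truth$lead, paste0("emg", midx)))
  role <- if (truth$lead == "right") "leading" else "trailing"
  bs <- spec$burst_specs
  brow <- bs[bs$muscle == muscle & bs$role == role, ]
  if (nrow(brow) != 1) stop("burst spec missing for ", muscle, "/", role)

  t_end <- max(truth$time)
  time <- seq(0, t_end, by = 1 / spec$emg_rate_hz)
  nn <- length(time)
  imp <- truth$hind_impacts
  K <- length(imp) - 1
  Tk <- diff(imp)

  o <- brow$onset_pct; f <- brow$offset_pct
  r_on <- if (o >= 100) o - 100 else if (o > f) o - 100 else o
  amp0 <- spec$emg_amplitude_v * brow$amp_scale * he$emg_gain[midx]
  amps <- amp0 * exp(stats::rnorm(K, 0, 0.10))

  env <- numeric(nn)
  on_s <- off_s <- numeric(K)
  for (k in seq_len(K)) {
    on_s[k] <- imp[k] + r_on / 100 * Tk[k]
    off_s[k] <- imp[k] + f / 100 * Tk[k]
    w <- edge_pct / 100 * Tk[k]
    env <- pmax(env, amps[k] * raised_cos_box(time, on_s[k], off_s[k], w))
  }

  carrier <- band_noise(nn, spec$emg_rate_hz)
  clean <- env * carrier
  # noise at the requested outside-burst RMS: mostly low-frequency movement
  # artefact (the reason for the 40 Hz high-pass) plus a broadband floor
  sigma <- mean(amps) * 10^(-spec$emg_snr_db / 20)
  noise <- sigma * (sqrt(0.91) * band_noise(nn, spec$emg_rate_hz, c(2, 35)) +
                      sqrt(0.09) * band_noise(nn, spec$emg_rate_hz))
  raw <- clean + noise + spec$emg_dc_offset_v

  arv_true <- vapply(seq_len(K), function(k) {
    w <- time >= imp[k] & time < imp[k + 1]
    mean(abs(clean[w]))
  }, numeric(1))
  ch <- emg_channel(time, raw, spec$emg_rate_hz, muscle,
                    horse = truth$horse, lead = truth$lead)
  list(channel = ch,
       truth = list(muscle = muscle, role = role,
                    onset_pct = rep(o, K), offset_pct = rep(f, K),
                    onset_s = on_s, offset_s = off_s,
                    arv_true = arv_true, amp = amps, snr_db = spec$emg_snr_db))
}

# raised-cosine-edged boxcar; edges of width w centred on the true edges
raised_cos_box <- function(t, on, off, w) {
  up <- (t - (on - w / 2)) / w
  dn <- ((off + w / 2) - t) / w
  e_up <- ifelse(up <= 0, 0, ifelse(up >= 1, 1, 0.5 - 0.5 * cos(pi * up)))
  e_dn <- ifelse(dn <= 0, 0, ifelse(dn >= 1, 1, 0.5 - 0.5 * cos(pi * dn)))
  pmin(e_up, e_dn)
}

# unit-RMS band-limited noise (default: the 20-450 Hz sEMG carrier band)
band_noise <- function(n, rate_hz, band = c(20, 450)) {
  x <- stats::rnorm(n)
  bf <- signal::butter(4, band / (rate_hz / 2), type = "pass")
  x <- as.numeric(signal::filtfilt(bf, x))
  x / sqrt(mean(x^2))
}

#' Write a full synthetic cohort to disk
#'
#' `n_horses x 2 leads` trials (markers, four sEMG channels each) plus one
#' static trial per horse, a YAML manifest and a ground-truth JSON sidecar.
#' Output is deterministic given the spec (same seed gives byte-identical
#' files).
#'
#' @param spec A [cohort_spec].
#' @param dir Output directory (must not exist unless `force`).
#' @param format Marker file format, `"csv"` (long) or `"trc"`.
#' @param force Overwrite an existing directory (default `FALSE`).
#' @return Invisibly, the manifest path.
#' @export
generate_cohort <- function(spec, dir, format = c("csv", "trc"),
                            force = FALSE) {
  format <- match.arg(format)
  if (dir.exists(dir)) {
    if (!force) stop("dataset directory '", dir,
                     "' exists; use force = TRUE to overwrite")
    unlink(dir, recursive = TRUE)
  }
  dir.create(dir, recursive = TRUE)
  muscles <- c("triceps", "splenius", "gluteal", "biceps")
  trials <- list()
  gt <- list()
  write_markers <- if (format == "trc") write_trc else write_markers_csv
  ext <- if (format == "trc") ".trc" else ".csv"
  for (h in seq_len(spec$n_horses)) {
    hid <- horse_id(h)
    static <- generate_static_trial(spec, h)
    static_file <- file.path(dir, paste0(hid, "_static", ext))
    write_markers(static, static_file)
    for (lead in c("left", "right")) {
      kin <- generate_kinematics(spec, h, lead)
      mf <- file.path(dir, paste0(hid, "_", lead, "_markers", ext))
      write_markers(kin$markers, mf)
      emg_files <- list()
      emg_truth <- list()
      for (m in muscles) {
        g <- generate_semg(spec, kin$truth, m)
        ef <- file.path(dir, paste0(hid, "_", lead, "_", m, ".csv"))
        write_emg_csv(g$channel, ef)
        emg_files[[m]] <- basename(ef)
        emg_truth[[m]] <- g$truth
      }
      trials[[length(trials) + 1]] <- list(
        horse = hid, lead = lead, markers = basename(mf),
        static = basename(static_file), emg = emg_files)
      tr <- kin$truth
      tr$angles_true <- NULL; tr$time <- NULL   # keep the sidecar compact
      tr$emg <- emg_truth
      gt[[paste0(hid, "_", lead)]] <- tr
    }
  }
  manifest <- list(
    dataset = list(kin_rate_hz = spec$kin_rate_hz,
                   emg_rate_hz = spec$emg_rate_hz,
                   mean_stride_s = spec$stride_duration_s,
                   marker_format = format,
                   muscles = as.list(muscles),
                   ground_truth = "ground_truth.json"),
    trials = trials)
  mp <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(mp)
}
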