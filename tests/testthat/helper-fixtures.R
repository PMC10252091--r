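# shared fixtures built in code

# single-marker set following a supplied y/z trajectory (x constant)
toy_markers <- function(time, y, z, rate, name = "m") {
  coords <- list()
  coords[[name]] <- cbind(0, y, z)
  marker_set(time, coords, rate)
}

# planar two-segment chain with an adjustable bend at the middle marker:
# proximal segment hangs straight down, distal bent by `bend_deg` about x
two_segment_markers <- function(bend_deg, n = 5, rate = 100) {
  time <- seq(0, (n - 1) / rate, by = 1 / rate)
  a <- matrix(rep(c(0, 0, 1000), each = n), n, 3)
  b <- matrix(rep(c(0, 0, 500), each = n), n, 3)
  th <- bend_deg * pi / 180
  cpt <- c(0, 500 * sin(th), 500 - 500 * cos(th))
  cc <- matrix(rep(cpt, each = n), n, 3)
  marker_set(time, list(prox = a, mid = b, dist = cc), rate)
}

two_segment_model <- function(sign = +1) {
  list(segments = data.frame(segment = c("upper", "lower"),
                             prox = c("prox", "mid"),
                             dist = c("mid", "dist"),
                             stringsAsFactors = FALSE),
       joints = data.frame(joint = "bend", prox_segment = "upper",
                           dist_segment = "lower", sign = sign,
                           stringsAsFactors = FALSE))
}

# pro-retraction fixture: body axis level, hoof tilted by `tilt_deg`
# (positive = cranial) from the vertical through the proximal landmark
proret_markers <- function(tilt_deg, limb = "fore", n = 4, rate = 100) {
  time <- seq(0, (n - 1) / rate, by = 1 / rate)
  len <- 1200
  th <- tilt_deg * pi / 180
  cst <- function(p) matrix(rep(p, each = n), n, 3)
  coords <- list(
    tubera_sacrale = cst(c(0, -500, 1500)),
    scapula_prox = cst(c(0, 500, 1500)),   # virtual landmark level with TS
    tuber_coxae = cst(c(0, -700, 1500)))
  prox <- if (limb == "fore") c(0, 500, 1500) else c(0, -700, 1500)
  hoof <- prox + c(0, len * sin(th), -len * cos(th))
  coords[[paste0(limb, "_hoof")]] <- cst(hoof)
  marker_set(time, coords, rate)
}

# long-format discrete table for mixed-model tests: one value per horse,
# limb role and stride, with a per-horse intercept
balanced_table <- function(n_horses = 10, strides = 1, effect = 0,
                           sd_within = 0.3, sd_horse = 0.5) {
  do.call(rbind, lapply(seq_len(n_horses), function(h) {
    base <- stats::rnorm(1, 0, sd_horse)
    data.frame(horse = sprintf("H%02d", h), lead = NA_character_,
               stride = rep(seq_len(strides), 2), muscle = NA_character_,
               variable = "v",
               limb_role = rep(c("Ld", "Tr"), each = strides),
               value = base + rep(c(effect, 0), each = strides) +
                 stats::rnorm(2 * strides, 0, sd_within))
  }))
}
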