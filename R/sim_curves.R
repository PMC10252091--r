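#' Simulate smooth Gaussian random curves
#'
#' White noise convolved with a Gaussian kernel of the requested FWHM and
#' scaled to unit pointwise variance; the standard null model for
#' validating random-field-theory inference on 1D fields.
#'
#' @param n Number of curves.
#' @param q Nodes per curve (default 101).
#' @param fwhm Kernel full width at half maximum in nodes.
#' @param seed Optional RNG seed.
#' @return `n` x `q` matrix.
#' @export
simulate_smooth_field <- function(n, q = 101, fwhm = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (fwhm <= 0) stop("fwhm must be positive")
  sd_k <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sd_k))
  kern <- stats::dnorm(seq(-half, half), sd = sd_k)
  kern <- kern / sqrt(sum(kern^2))          # unit output variance
  pad <- q + 2 * half
  out <- matrix(0, n, q)
  for (i in seq_len(n)) {
    w <- stats::rnorm(pad)
    s <- stats::filter(w, kern, sides = 2)
    out[i, ] <- s[(half + 1):(half + q)]
  }
  out
}

#' Simulate a curve-level canter cohort for waveform inference studies
#'
#' Per-horse baseline curves plus smooth within-horse stride-to-stride
#' noise, averaged into per-horse condition means (the paired analysis
#' unit). An optional condition offset of `effect` (in units of the
#' within-horse SD) is added to condition B over `effect_window` (% stride).
#' With `effect = 0` the comparison is exactly null.
#'
#' @param n_horses Horses (default 10).
#' @param strides_per_cond Strides averaged per horse and condition (6).
#' @param fwhm Smoothness of the within-horse noise in nodes (default 15,
#'   typical of stride-normalized gait curves).
#' @param sd_within Within-horse stride-to-stride SD at a node (default 1).
#' @param effect Offset added to condition B, in multiples of `sd_within`.
#' @param effect_window Nodes (in % stride) receiving the offset.
#' @param seed Optional RNG seed.
#' @return List: `a`, `b` (horse-mean curve matrices, one row per horse).
#' @export
simulate_curve_cohort <- function(n_horses = 10, strides_per_cond = 6,
                                  fwhm = 15, sd_within = 1, effect = 0,
                                  effect_window = c(40, 60), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- 101
  w <- (0:(q - 1)) >= effect_window[1] & (0:(q - 1)) <= effect_window[2]
  a <- matrix(0, n_horses, q)
  b <- matrix(0, n_horses, q)
  for (h in seq_len(n_horses)) {
    baseline <- 3 * simulate_smooth_field(1, q, fwhm)
    sa <- baseline[rep(1, strides_per_cond), , drop = FALSE] +
      sd_within * simulate_smooth_field(strides_per_cond, q, fwhm)
    sb <- baseline[rep(1, strides_per_cond), , drop = FALSE] +
      sd_within * simulate_smooth_field(strides_per_cond, q, fwhm)
    sb[, w] <- sb[, w] + effect * sd_within
    a[h, ] <- colMeans(sa)
    b[h, ] <- colMeans(sb)
  }
  list(a = a, b = b)
}
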