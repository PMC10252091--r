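#' Time-normalize a series onto the 101-point stride cycle
#'
#' Linear interpolation of a uniformly sampled series onto 101 equally
#' spaced points spanning the stride window (0, 1, ..., 100 % of the
#' cycle).
#'
#' @param values Numeric series.
#' @param time Sample times (seconds).
#' @param window Stride window `c(start_s, end_s)`.
#' @param n_points Number of points (default 101).
#' @return Numeric vector of length `n_points`.
#' @export
time_normalize <- function(values, time, window, n_points = 101) {
  stopifnot(window[2] > window[1], sum(time >= window[1] & time <= window[2]) >= 2)
  xout <- seq(window[1], window[2], length.out = n_points)
  stats::approx(time, values, xout = xout, rule = 2)$y
}

#' Per-horse per-condition mean curves
#'
#' Averages stride curves within horse and condition; horses missing either
#' condition are excluded with a warning. The per-horse mean curve is the
#' analysis unit of the paired waveform comparison.
#'
#' @param curves Matrix, one stride curve per row.
#' @param horse,condition Vectors labelling the rows.
#' @return List: `values` (matrix of mean curves), `horse`, `condition`.
#' @export
subject_means <- function(curves, horse, condition) {
  stopifnot(nrow(curves) == length(horse), length(horse) == length(condition))
  conds <- sort(unique(condition))
  full <- vapply(unique(horse), function(h)
    all(conds %in% condition[horse == h]), logical(1))
  if (any(!full)) {
    warning("excluding horse(s) missing a condition: ",
            paste(unique(horse)[!full], collapse = ", "))
  }
  keep_h <- unique(horse)[full]
  keep <- horse %in% keep_h
  key <- droplevels(interaction(horse[keep], condition[keep], drop = TRUE,
                                sep = "\r"))
  means <- rowsum(curves[keep, , drop = FALSE], key)
  counts <- as.vector(table(key)[rownames(means)])
  means <- means / counts
  lab <- do.call(rbind, strsplit(rownames(means), "\r", fixed = TRUE))
  list(values = unname(means), horse = lab[, 1], condition = lab[, 2])
}

#' Node-wise paired t-field
#'
#' Paired t statistic at every node of the difference curves `a - b`, rows
#' aligned by subject. Nodes with zero variance give infinite t and are
#' flagged.
#'
#' @param a,b Matrices of per-subject curves (same subjects, same order).
#' @return List: `t` (field), `df` (= n - 1), `diff` (difference matrix),
#'   `zero_var` (logical flag per node).
#' @export
paired_t_field <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)), nrow(a) >= 2)
  d <- a - b
  n <- nrow(d)
  m <- colMeans(d)
  s <- sqrt(colSums((d - rep(m, each = n))^2) / (n - 1))
  tt <- ifelse(s > 0, m / (s / sqrt(n)), sign(m) * Inf)
  tt[s == 0 & m == 0] <- 0
  list(t = tt, df = n - 1, diff = d, zero_var = s == 0 & m != 0)
}

#' Estimate field smoothness (FWHM) and resel count from residuals
#'
#' Smoothness of the residual field expressed as the full width at half
#' maximum of an equivalent Gaussian kernel: residual curves are normalized
#' to unit pointwise variance, their gradient is taken by central
#' differences, and `FWHM = sqrt(4 log 2 / mean gradient variance)`.
#' Resels = (Q - 1) / FWHM. Constant residuals give infinite FWHM and zero
#' resels.
#'
#' @param residuals Matrix of residual curves (one per row).
#' @return List: `fwhm` (nodes), `resels`.
#' @export
estimate_fwhm <- function(residuals) {
  stopifnot(is.matrix(residuals), nrow(residuals) >= 2)
  q <- ncol(residuals)
  v <- colSums(residuals^2)
  if (all(v < 1e-300)) return(list(fwhm = Inf, resels = 0))
  u <- residuals / rep(sqrt(pmax(v, 1e-300)), each = nrow(residuals))
  g <- t(apply(u, 1, deriv_central, rate_hz = 1))   # node spacing = 1
  lambda <- colSums(g^2)
  lam <- mean(lambda)
  if (lam <= 0) return(list(fwhm = Inf, resels = 0))
  fwhm <- sqrt(4 * log(2) / lam)
  list(fwhm = fwhm, resels = (q - 1) / fwhm)
}

# Euler characteristic densities of a 1D t-field (unit search volume)
ec_density_t <- function(t, df, resels) {
  stats::pt(t, df, lower.tail = FALSE) +
    resels * sqrt(4 * log(2)) / (2 * pi) *
      (1 + t^2 / df)^(-(df - 1) / 2)
}

#' Random-field-theory critical threshold for a 1D t-field
#'
#' The smallest t at which the expected Euler characteristic of the
#' thresholded field falls to the test level: for a two-sided test at
#' `alpha`, the positive and negative excursions each get `alpha / 2`.
#' With zero resels this reduces to the ordinary critical t.
#'
#' @param df Degrees of freedom (>= 1).
#' @param resels Resel count (>= 0).
#' @param alpha Family-wise error level (default 0.05).
#' @param two_sided Split `alpha` over both tails (default `TRUE`).
#' @return Critical threshold `t_star` (> 0).
#' @export
rft_threshold <- function(df, resels, alpha = 0.05, two_sided = TRUE) {
  stopifnot(df >= 1, resels >= 0, alpha > 0, alpha < 1)
  target <- if (two_sided) alpha / 2 else alpha
  f <- function(t) ec_density_t(t, df, resels) - target
  if (f(100) > 0) stop("no RFT threshold below t = 100")
  stats::uniroot(f, c(0, 100), tol = 1e-10)$root
}

#' Suprathreshold cluster inference for a 1D t-field
#'
#' Maximal runs where `|t| > t_star` become clusters; each gets a
#' family-wise corrected p-value from the standard 1D random-field cluster-
#' extent approximation: with expected cluster count `m` (from the EC
#' density of the |t| field at the threshold) and expected cluster extent
#' `eta` in resel units, `P(extent >= k) = exp(-pi k^2 / (4 eta^2))` and
#' `p = 1 - exp(-m P(extent >= k))`.
#'
#' Infinite t values (zero-variance nodes) are clipped to the finite field
#' maximum for cluster formation.
#'
#' @param t_field t statistics over the 101 nodes.
#' @param t_star Critical threshold from [rft_threshold()].
#' @param fwhm Field smoothness in nodes.
#' @param df Degrees of freedom.
#' @return Data frame: `start_pct`, `end_pct`, `extent` (nodes), `p_value`.
#' @export
cluster_inference <- function(t_field, t_star, fwhm, df) {
  q <- length(t_field)
  tt <- t_field
  if (any(is.infinite(tt))) {
    mx <- max(abs(tt[is.finite(tt)]), t_star + 1)
    tt[is.infinite(tt)] <- sign(tt[is.infinite(tt)]) * mx
  }
  over <- abs(tt) > t_star
  empty <- data.frame(start_pct = numeric(), end_pct = numeric(),
                      extent = integer(), p_value = numeric())
  if (!any(over)) return(empty)
  r <- rle(over)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ks <- which(r$values)
  resels <- (q - 1) / fwhm
  # expected number of |t| clusters at the threshold and expected extent
  m <- 2 * ec_density_t(t_star, df, resels)
  en <- q * 2 * stats::pt(t_star, df, lower.tail = FALSE) / fwhm
  eta <- max(en / m, 1e-12)
  out <- lapply(ks, function(k) {
    ext <- r$lengths[k]
    k_res <- ext / fwhm
    p_unc <- exp(-pi * k_res^2 / (4 * eta^2))
    p <- 1 - exp(-m * p_unc)
    data.frame(start_pct = starts[k] - 1, end_pct = ends[k] - 1,
               extent = ext, p_value = min(max(p, 1e-16), 1))
  })
  do.call(rbind, out)
}

#' Sign-flip permutation threshold for a paired t-field
#'
#' Null distribution of the field-wide maximum |t| over sign permutations
#' of the difference curves. When `n_perm >= 2^n` (or `exhaustive = TRUE`)
#' all `2^n` sign patterns are enumerated; otherwise `n_perm` random
#' patterns are drawn (deterministically under `seed`).
#'
#' @param d Matrix of difference curves, one subject per row (n >= 4).
#' @param alpha Test level (default 0.05).
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed for sampled permutations.
#' @return List: `t_star` ((1 - alpha) quantile of max |t|), `max_t` (null
#'   distribution), `n_perm_used`, `exhaustive`.
#' @export
permutation_threshold <- function(d, alpha = 0.05, n_perm = 1000,
                                  seed = NULL) {
  stopifnot(is.matrix(d), nrow(d) >= 4)
  n <- nrow(d)
  exhaustive <- n <= 20 && n_perm >= 2^n
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    if (!is.null(seed)) set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    nrow = n_perm)
  }
  ss <- colSums(d^2)
  mm <- (signs %*% d) / n
  vv <- (matrix(ss, nrow(signs), ncol(d), byrow = TRUE) - n * mm^2) / (n - 1)
  tt <- abs(mm) / sqrt(pmax(vv, 1e-300) / n)
  max_t <- apply(tt, 1, max)
  list(t_star = stats::quantile(max_t, 1 - alpha, names = FALSE),
       max_t = max_t, n_perm_used = nrow(signs), exhaustive = exhaustive)
}

#' Paired 1D SPM comparison of two waveform conditions
#'
#' Fits the node-wise paired t-field on per-subject difference curves,
#' estimates residual smoothness, computes the random-field-theory critical
#' threshold at `alpha` (two-sided) and performs suprathreshold cluster
#' inference.
#'
#' @param a,b Matrices of per-subject 101-point curves, rows aligned by
#'   subject.
#' @param alpha Family-wise error level (default 0.05).
#' @param two_sided Two-sided test (default `TRUE`).
#' @param variable Optional label carried into the result.
#' @return Object of class `spm_paired`: `t` field, `df`, `fwhm`, `resels`,
#'   `t_star`, `alpha`, `clusters`, plus the condition means/SDs for
#'   plotting.
#' @export
spm_paired <- function(a, b, alpha = 0.05, two_sided = TRUE,
                       variable = NA_character_) {
  tf <- paired_t_field(a, b)
  resid <- tf$diff - rep(colMeans(tf$diff), each = nrow(tf$diff))
  sm <- estimate_fwhm(resid)
  t_star <- rft_threshold(tf$df, sm$resels, alpha, two_sided)
  clusters <- cluster_inference(tf$t, t_star, sm$fwhm, tf$df)
  structure(list(t = tf$t, df = tf$df, fwhm = sm$fwhm, resels = sm$resels,
                 t_star = t_star, alpha = alpha, clusters = clusters,
                 zero_var = tf$zero_var, variable = variable,
                 mean_a = colMeans(a), mean_b = colMeans(b),
                 sd_a = apply(a, 2, stats::sd), sd_b = apply(b, 2, stats::sd),
                 n = nrow(a)),
            class = "spm_paired")
}

#' @export
print.spm_paired <- function(x, ...) {
  cat("Paired 1D SPM", if (!is.na(x$variable)) paste0(" [", x$variable, "]"),
      ": n = ", x$n, ", df = ", x$df, "\n", sep = "")
  cat(sprintf("  FWHM = %.2f nodes, resels = %.2f, t* = %.3f (alpha = %g)\n",
              x$fwhm, x$resels, x$t_star, x$alpha))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %d: %g-%g%% stride, p = %.4g\n", i,
                  x$clusters$start_pct[i], x$clusters$end_pct[i],
                  x$clusters$p_value[i]))
  }
  invisible(x)
}

#' @export
summary.spm_paired <- function(object, ...) {
  print(object)
  invisible(list(t_max = max(abs(object$t[is.finite(object$t)])),
                 t_star = object$t_star, clusters = object$clusters))
}

#' Plot a paired SPM result
#'
#' Two panels in the conventional layout: condition mean +/- SD curves on
#' top, the t-field with the critical threshold and shaded significant
#' clusters below.
#'
#' @param x An `spm_paired` object.
#' @param labels Condition labels (length 2).
#' @param ... Unused.
#' @export
plot.spm_paired <- function(x, labels = c("A", "B"), ...) {
  pct <- 0:(length(x$t) - 1)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ylim <- range(x$mean_a + x$sd_a, x$mean_a - x$sd_a,
                x$mean_b + x$sd_b, x$mean_b - x$sd_b)
  plot(pct, x$mean_a, type = "n", ylim = ylim, xlab = "% stride",
       ylab = x$variable %||% "value", main = "condition means +/- SD")
  graphics::polygon(c(pct, rev(pct)),
                    c(x$mean_a + x$sd_a, rev(x$mean_a - x$sd_a)),
                    col = grDevices::adjustcolor("red", 0.2), border = NA)
  graphics::polygon(c(pct, rev(pct)),
                    c(x$mean_b + x$sd_b, rev(x$mean_b - x$sd_b)),
                    col = grDevices::adjustcolor("black", 0.2), border = NA)
  graphics::lines(pct, x$mean_a, col = "red")
  graphics::lines(pct, x$mean_b, col = "black")
  graphics::legend("topright", legend = labels, col = c("red", "black"),
                   lty = 1, bty = "n")
  tt <- x$t; tt[is.infinite(tt)] <- NA
  plot(pct, tt, type = "l", xlab = "% stride", ylab = "SPM{t}",
       main = sprintf("paired t-field, t* = %.2f", x$t_star))
  graphics::abline(h = c(-x$t_star, x$t_star), col = "red", lty = 2)
  if (nrow(x$clusters) > 0)
    for (i in seq_len(nrow(x$clusters)))
      graphics::rect(x$clusters$start_pct[i], graphics::par("usr")[3],
                     x$clusters$end_pct[i], graphics::par("usr")[4],
                     col = grDevices::adjustcolor("grey", 0.4), border = NA)
  invisible(x)
}
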