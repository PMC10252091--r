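test_that("time normalization is exact for aligned and linear inputs", {
  t101 <- seq(0, 1, length.out = 101)
  x <- sin(2 * pi * t101)
  expect_equal(time_normalize(x, t101, c(0, 1)), x, tolerance = 1e-12)
  # linear ramp maps to a linear ramp with endpoints preserved
  t <- seq(0, 0.6, by = 1 / 232)
  y <- 3 + 7 * t
  out <- time_normalize(y, t, c(0, 0.59))
  expect_equal(out, 3 + 7 * seq(0, 0.59, length.out = 101), tolerance = 1e-9)
  expect_equal(length(out), 101)
  # 232 Hz sinusoid over one stride: interpolation error < 0.1% amplitude
  f <- 3
  y2 <- sin(2 * pi * f * t)
  out2 <- time_normalize(y2, t, c(0, 0.59))
  truth <- sin(2 * pi * f * seq(0, 0.59, length.out = 101))
  expect_lt(max(abs(out2 - truth)), 1e-3)
})

test_that("subject means average strides within horse and condition", {
  curves <- rbind(rep(1, 101), rep(3, 101), rep(5, 101), rep(5, 101))
  sm <- subject_means(curves, c("H1", "H1", "H2", "H2"),
                      c("a", "b", "a", "b"))
  expect_equal(nrow(sm$values), 4)
  # two identical strides give the same curve
  sm2 <- subject_means(rbind(rep(2, 101), rep(2, 101), rep(7, 101)),
                       c("H1", "H1", "H1"), c("a", "a", "b"))
  expect_equal(sm2$values[sm2$condition == "a", ], rep(2, 101))
  # a horse missing one condition is excluded with a warning
  expect_warning(
    sm3 <- subject_means(curves[1:3, ], c("H1", "H1", "H2"),
                         c("a", "b", "a")), "H2")
  expect_equal(unique(sm3$horse), "H1")
})

test_that("the paired t-field equals the scalar paired t-test at every node", {
  set.seed(11)
  a <- matrix(rnorm(8 * 101), 8, 101)
  b <- matrix(rnorm(8 * 101), 8, 101)
  tf <- paired_t_field(a, b)
  expect_equal(tf$df, 7)
  for (j in c(1, 27, 64, 101)) {
    oracle <- t.test(a[, j], b[, j], paired = TRUE)$statistic
    expect_equal(tf$t[j], unname(oracle), tolerance = 1e-12)
  }
  expect_equal(paired_t_field(a, a)$t, rep(0, 101))
  expect_equal(paired_t_field(b, a)$t, -tf$t)
  # constant differences {1,2,3}: t = 2 / (1/sqrt(3)) = 2 sqrt(3)
  a3 <- matrix(rep(c(1, 2, 3), 101), 3, 101)
  tf3 <- paired_t_field(a3, matrix(0, 3, 101))
  expect_equal(tf3$t, rep(2 * sqrt(3), 101), tolerance = 1e-12)
  # zero-variance non-zero-mean nodes flagged as infinite
  a0 <- matrix(rep(c(1, 1, 1), 101), 3, 101)
  tf0 <- paired_t_field(a0, matrix(0, 3, 101))
  expect_true(all(is.infinite(tf0$t)))
  expect_true(all(tf0$zero_var))
})

test_that("FWHM estimation recovers known smoothness", {
  set.seed(21)
  # unsmoothed noise: FWHM about 2 nodes
  f <- replicate(100, estimate_fwhm(matrix(rnorm(10 * 101), 10, 101))$fwhm)
  expect_equal(mean(f), 2.0, tolerance = 0.5)
  # kernel of FWHM 20 recovered
  f20 <- mean(replicate(60,
    estimate_fwhm(simulate_smooth_field(10, 101, 20))$fwhm))
  expect_equal(f20, 20, tolerance = 3)
  # resels decrease monotonically with smoothing
  r <- vapply(c(5, 10, 20, 40), function(w) {
    mean(replicate(30, estimate_fwhm(simulate_smooth_field(8, 101, w))$resels))
  }, numeric(1))
  expect_true(all(diff(r) < 0))
  # constant residuals: infinite smoothness, zero resels
  expect_equal(estimate_fwhm(matrix(1, 4, 101))$resels, 0)
})

test_that("the RFT threshold has its limiting and monotone properties", {
  # zero resels: ordinary two-sided critical t
  expect_equal(rft_threshold(9, 0), qt(0.975, 9), tolerance = 1e-6)
  expect_equal(rft_threshold(15, 0, alpha = 0.01), qt(0.995, 15),
               tolerance = 1e-6)
  ts <- vapply(c(0, 2, 5, 10, 20), function(r) rft_threshold(9, r),
               numeric(1))
  expect_true(all(diff(ts) > 0))
})

test_that("the RFT threshold matches a Monte-Carlo max-|t| oracle", {
  set.seed(33)
  t_star <- rft_threshold(9, 10)
  mx <- replicate(3000, {
    d <- simulate_smooth_field(10, 101, fwhm = 10)   # resels ~ 10
    max(abs(paired_t_field(d, matrix(0, 10, 101))$t))
  })
  expect_equal(t_star, unname(quantile(mx, 0.95)), tolerance = 0.05)
})

test_that("cluster inference forms maximal runs with monotone p-values", {
  tfield <- rep(0, 101)
  expect_equal(nrow(cluster_inference(tfield, 3.5, 10, 9)), 0)
  tfield[40:55] <- 5
  cl <- cluster_inference(tfield, 3.5, 10, 9)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start_pct, cl$end_pct), c(39, 54))
  expect_true(cl$p_value > 0 && cl$p_value <= 1)
  # p decreases as the extent grows at fixed threshold
  p <- vapply(c(4, 8, 16, 30), function(k) {
    tf <- rep(0, 101); tf[10 + seq_len(k)] <- 5
    cluster_inference(tf, 3.5, 10, 9)$p_value
  }, numeric(1))
  expect_true(all(diff(p) < 0))
  # negative excursions cluster too
  tfield2 <- rep(0, 101); tfield2[70:80] <- -6
  expect_equal(nrow(cluster_inference(tfield2, 3.5, 10, 9)), 1)
})

test_that("sign-flip permutation oracle is exhaustive, seeded, calibrated", {
  set.seed(5)
  d <- matrix(rnorm(4 * 101), 4, 101)
  p <- permutation_threshold(d, n_perm = 1000)
  expect_true(p$exhaustive)
  expect_equal(p$n_perm_used, 16)
  d8 <- matrix(rnorm(8 * 51), 8, 51)
  p1 <- permutation_threshold(d8, n_perm = 100, seed = 9)
  p2 <- permutation_threshold(d8, n_perm = 100, seed = 9)
  expect_identical(p1$t_star, p2$t_star)
  # RFT and permutation thresholds agree on smooth null fields
  set.seed(71)
  rel <- replicate(8, {
    d <- simulate_smooth_field(10, 101, 15)
    sm <- estimate_fwhm(d - rep(colMeans(d), each = 10))
    rft_threshold(9, sm$resels) / permutation_threshold(d, n_perm = 1024)$t_star
  })
  expect_lt(abs(mean(rel) - 1), 0.1)
})

test_that("spm_paired assembles a coherent result object", {
  set.seed(14)
  cc <- simulate_curve_cohort(10, 6, fwhm = 15, effect = 2, seed = 3)
  s <- spm_paired(cc$a, cc$b, variable = "toy")
  expect_s3_class(s, "spm_paired")
  expect_equal(s$df, 9)
  expect_length(s$t, 101)
  expect_gt(s$t_star, qt(0.975, 9))
  expect_gte(nrow(s$clusters), 1)
  expect_true(all(abs(s$t[s$clusters$start_pct[1]:s$clusters$end_pct[1] + 1]) >
                    s$t_star))
  expect_output(print(s), "cluster")
  # plot method draws without error
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(s); grDevices::dev.off()
  expect_true(file.exists(f))
  unlink(f)
})
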