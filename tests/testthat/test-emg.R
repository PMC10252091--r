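rate <- 2088

test_that("preprocessing removes DC and low-frequency content, rectifies", {
  t <- seq(0, 2, by = 1 / rate)
  ch <- emg_channel(t, rep(0.3, length(t)), rate)
  expect_lt(max(preprocess_emg(ch)$values), 1e-8)
  # 10 Hz movement artefact suppressed by the 40 Hz high-pass
  ch10 <- emg_channel(t, sin(2 * pi * 10 * t), rate)
  out <- preprocess_emg(ch10)$values
  i <- t > 0.3 & t < 1.7
  expect_lt(sqrt(mean(out[i]^2)), 0.01 * sqrt(0.5))
  # 200 Hz passband tone: rectified mean = 2A/pi
  A <- 0.002
  ch200 <- emg_channel(t, A * sin(2 * pi * 200 * t), rate)
  out <- preprocess_emg(ch200)$values
  expect_equal(mean(out[i]), 2 * A / pi, tolerance = 0.02)
  expect_error(preprocess_emg(emg_channel(t, t, 800)), "alias")
})

test_that("stride ARV is the windowed mean of the rectified signal", {
  tt <- seq(0, 0.3, by = 0.1)
  expect_equal(stride_arv(rep(2, 4), tt, c(0, 0.4)), 2)
  expect_equal(stride_arv(c(0, 1, 2, 3), tt, c(0, 0.4)), 1.5)
  expect_error(stride_arv(c(0, 1), c(0, 1), c(2, 3)), "empty")
})

test_that("Tukey fences flag spurious strides and never raise the max", {
  x <- c(1, 1.1, 0.9, 1.05, 10)
  fl <- flag_arv_outliers(x)
  expect_equal(which(fl), 5L)
  expect_false(any(flag_arv_outliers(rep(2, 6))))
  expect_error(flag_arv_outliers(c(1, 2, 3)), "at least 4")
  set.seed(2)
  for (i in 1:20) {
    v <- stats::rlnorm(12)
    fl <- flag_arv_outliers(v)
    expect_lte(max(v[!fl]), max(v))
  }
})

test_that("ARV normalization maps the surviving max to 100 and is scale-free", {
  expect_equal(normalize_arv(c(1, 2, 4)), c(25, 50, 100))
  x <- c(1, 1.1, 0.9, 1.05, 10)
  fl <- flag_arv_outliers(x)
  out <- normalize_arv(x, fl)
  expect_true(is.na(out[5]))
  expect_equal(max(out, na.rm = TRUE), 100)
  for (c0 in c(0.01, 3, 1e4))
    expect_equal(normalize_arv(x * c0, fl), out)
  expect_error(normalize_arv(rep(0, 4)), "zero")
})

test_that("envelopes preserve constants and smooth in order of cut-off", {
  t <- seq(0, 2, by = 1 / rate)
  expect_equal(emg_envelope(rep(0.5, length(t)), 25, rate_hz = rate),
               rep(0.5, length(t)), tolerance = 1e-8)
  set.seed(3)
  x <- abs(rnorm(length(t)))
  tv <- function(v) sum(abs(diff(v)))
  e25 <- emg_envelope(x, 25, rate_hz = rate)
  e10 <- emg_envelope(x, 10, rate_hz = rate)
  expect_lt(tv(e10), tv(e25))
  expect_lt(tv(e25), tv(x))
})

test_that("envelope half-maximum crossings sit near boxcar burst edges", {
  t <- seq(0, 1, by = 1 / rate)
  x <- as.numeric(t >= 0.3 & t <= 0.6)
  e <- emg_envelope(x, 25, rate_hz = rate)
  half <- 0.5 * max(e)
  on <- t[min(which(e > half))]
  off <- t[max(which(e > half))]
  expect_lt(abs(on - 0.3), 0.010)
  expect_lt(abs(off - 0.6), 0.010)
})

test_that("RVC normalization uses the screened per-stride peak maximum", {
  t <- seq(0, 6, by = 1 / 200)
  windows <- data.frame(start_s = 0:5, end_s = 1:6)
  env <- rep(1, length(t))
  for (k in 0:5) env[t >= k + 0.4 & t < k + 0.6] <- 2 + 0.1 * k
  out <- rvc_normalize(env, t, windows)
  expect_equal(max(out$pct), 100)                       # RVC stride peak
  expect_equal(out$rvc, 2.5)
  expect_equal(rvc_normalize(env * 7, t, windows)$pct, out$pct)
  # a spike stride is excluded from the RVC but still normalized > 100%
  env2 <- env; env2[t >= 2.4 & t < 2.5] <- 40
  out2 <- rvc_normalize(env2, t, windows)
  expect_true(out2$peak_outlier[3])
  expect_equal(out2$rvc, 2.5)
  expect_gt(max(out2$pct), 100)
})

test_that("double-threshold detector follows its amplitude and timing rules", {
  t <- seq(0, 6, by = 1 / rate)
  windows <- data.frame(start_s = 0:5, end_s = 1:6)
  mk <- function(v) structure(list(time = t, values = v, rate_hz = rate),
                              class = "emg_channel")
  expect_equal(nrow(detect_bursts(mk(rep(0, length(t))), windows, 1)), 0)
  # clean boxcar bursts 20-50% of each 1 s stride
  v <- ifelse((t %% 1) >= 0.2 & (t %% 1) <= 0.5, 1, 0.001)
  b <- detect_bursts(mk(v), windows, 1, use_envelope = FALSE)
  main <- b[b$is_main, ]
  expect_equal(nrow(main), 6)
  expect_equal(main$onset_pct, rep(20, 6), tolerance = 1)
  expect_equal(main$offset_pct, rep(50, 6), tolerance = 1)
  expect_true(all(main$duration_pct > 0 & main$duration_pct <= 100))
  # a 2%-of-stride blip fails the timing threshold
  v2 <- rep(0.001, length(t)); v2[t >= 2.3 & t <= 2.32] <- 1
  expect_equal(nrow(detect_bursts(mk(v2), windows, 1, use_envelope = FALSE)), 0)
  # sub-threshold gaps shorter than the timing threshold are bridged
  v3 <- v; v3[t >= 1.3 & t <= 1.33] <- 0.001
  b3 <- detect_bursts(mk(v3), windows, 1, use_envelope = FALSE)
  expect_equal(sum(b3$stride == 2), 1)
})

test_that("raising the amplitude threshold never lengthens a burst", {
  spec <- cohort_spec(n_horses = 1, strides_per_lead = 4, seed = 6)
  kin <- generate_kinematics(spec, 1, "left")
  g <- generate_semg(spec, kin$truth, "gluteal")
  rect <- preprocess_emg(g$channel)
  st <- kin$truth$strides
  prev <- NULL
  for (af in c(0.03, 0.05, 0.10, 0.20)) {
    b <- detect_bursts(rect, st, 0.59, amp_frac = af)
    tot <- sum(b$offset_s - b$onset_s)
    if (!is.null(prev)) expect_lte(tot, prev + 1e-9)
    prev <- tot
  }
})

test_that("burst timing outputs respect the stride-relative contracts", {
  spec <- cohort_spec(n_horses = 2, strides_per_lead = 5, seed = 7)
  for (m in c("triceps", "biceps")) {
    kin <- generate_kinematics(spec, 1, "right")
    g <- generate_semg(spec, kin$truth, m)
    b <- detect_bursts(preprocess_emg(g$channel), kin$truth$strides, 0.59)
    expect_true(all(b$onset_pct >= 0 & b$onset_pct < 200))
    expect_true(all(b$duration_pct > 0 & b$duration_pct <= 100))
    for (s in unique(b$stride))
      expect_equal(sum(b$is_main[b$stride == s]), 1)
  }
})

test_that("peak timing uses the 10 Hz envelope argmax with earliest ties", {
  t <- seq(0, 1, by = 1 / rate)
  tri <- pmax(0, 1 - abs(t - 0.35) / 0.15)          # symmetric peak at 35%
  e <- emg_envelope(tri, 10, rate_hz = rate)
  expect_equal(peak_timing(e, t, c(0, 1)), 35, tolerance = 1)
  expect_gt(peak_timing(t, t, c(0, 1)), 99)          # monotone -> end
  expect_equal(peak_timing(rep(2, length(t)), t, c(0, 1)), 0)  # tie -> 0
})

test_that("boundary-straddling onsets wrap by +100", {
  expect_equal(wrap_onsets(c(95, 98, 2)), c(95, 98, 102))
  expect_equal(wrap_onsets(c(96, 1.8, 88)), c(96, 101.8, 88))
  expect_equal(wrap_onsets(c(25, 40, 79)), c(25, 40, 79))
  expect_equal(wrap_onsets(c(5, 10, 15)), c(5, 10, 15))   # no straddle
})

test_that("detector recovery holds across the cohort at default SNR", {
  spec <- cohort_spec(n_horses = 2, strides_per_lead = 6, seed = 31)
  err <- c()
  for (h in 1:2) for (lead in c("left", "right")) {
    kin <- generate_kinematics(spec, h, lead)
    st <- kin$truth$strides
    for (m in c("triceps", "splenius", "gluteal", "biceps")) {
      g <- generate_semg(spec, kin$truth, m)
      b <- detect_bursts(preprocess_emg(g$channel), st, 0.59)
      main <- b[b$is_main, ]
      for (k in seq_len(nrow(st))) {
        r <- main[main$stride == k, ]
        if (nrow(r) == 0) { err <- c(err, Inf); next }
        err <- c(err,
                 abs(r$onset_s - g$truth$onset_s[k]) /
                   st$stride_duration_s[k] * 100,
                 abs(r$offset_s - g$truth$offset_s[k]) /
                   st$stride_duration_s[k] * 100)
      }
    }
  }
  expect_gte(mean(err <= 2), 0.95)
})
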