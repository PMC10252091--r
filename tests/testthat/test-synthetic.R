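test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(hind_stance_s = 0.7), "shorter than the stride")
  expect_error(cohort_spec(fore_stance_s = 0.45), "overrun|shorter")
  expect_error(cohort_spec(emg_rate_hz = 500), "emg_rate_hz")
  bs <- default_burst_specs(); bs$onset_pct[1] <- 230
  expect_error(cohort_spec(burst_specs = bs))
})

test_that("zero forward velocity leaves the trunk marker in place", {
  spec <- cohort_spec(n_horses = 1, strides_per_lead = 3,
                      stride_velocity_mps = 0,
                      effect_sizes = list(stride_velocity_mps = 0), seed = 2)
  kin <- generate_kinematics(spec, 1, "left")
  y <- kin$markers$coords$tubera_sacrale[, 2]
  expect_lt(diff(range(y)), 120)      # only the within-stride oscillation
})

test_that("generated stride durations match the spec within jitter", {
  spec <- cohort_spec(n_horses = 4, strides_per_lead = 6, seed = 10)
  durs <- c()
  for (h in 1:4) for (lead in c("left", "right"))
    durs <- c(durs,
              generate_kinematics(spec, h, lead)$truth$strides$stride_duration_s)
  expect_equal(mean(durs), 0.59, tolerance = 0.02)
  expect_lt(sd(durs), 0.05)
})

test_that("the footfall pattern places the diagonal at the stated ratio", {
  spec <- cohort_spec(n_horses = 2, strides_per_lead = 5, seed = 3)
  frame <- 1 / spec$kin_rate_hz
  for (lead in c("left", "right")) {
    kin <- generate_kinematics(spec, 2, lead)
    tr <- kin$truth
    expect_true(all(diff(tr$hind_impacts) > 0))
    # hind impact < fore impact < fore liftoff < next hind impact
    K <- nrow(tr$strides)
    expect_true(all(tr$fore_impacts[1:K] > tr$hind_impacts[1:K]))
    expect_true(all(tr$fore_liftoffs[1:K] < tr$hind_impacts[2:(K + 1)]))
    # diagonal (LdH-TrF) placement at 55.5% of the hind stance
    adv <- tr$fore_impacts - tr$hind_impacts
    stance <- tr$hind_liftoffs - tr$hind_impacts
    expect_lt(max(abs(adv - 0.555 * stance)), frame + 3 * 0.002)
    # exactly one stance per limb per stride
    for (k in seq_len(K)) {
      expect_equal(sum(tr$fore_impacts >= tr$hind_impacts[k] &
                         tr$fore_impacts < tr$hind_impacts[k + 1]), 1)
    }
  }
})

test_that("synthetic sEMG honours its SNR and seed contracts", {
  spec <- cohort_spec(n_horses = 1, strides_per_lead = 5, seed = 20)
  kin <- generate_kinematics(spec, 1, "right")
  g <- generate_semg(spec, kin$truth, "splenius")
  x <- g$channel$values - mean(g$channel$values)
  tt <- g$channel$time
  inb <- rep(FALSE, length(tt)); outb <- TRUE
  st <- kin$truth$strides
  for (k in seq_len(nrow(st))) {
    inb <- inb | (tt > g$truth$onset_s[k] + 0.03 &
                    tt < g$truth$offset_s[k] - 0.03)
    outb <- outb & !(tt > g$truth$onset_s[k] - 0.05 &
                       tt < g$truth$offset_s[k] + 0.05)
  }
  snr <- 20 * log10(sqrt(mean(x[inb]^2)) / sqrt(mean(x[outb]^2)))
  expect_lt(abs(snr - spec$emg_snr_db), 1)
  # same burst spec, different seed: same true windows, different samples
  spec2 <- cohort_spec(n_horses = 1, strides_per_lead = 5, seed = 77)
  kin2 <- generate_kinematics(spec, 1, "right")   # same kinematic truth
  g2 <- generate_semg(spec2, kin2$truth, "splenius")
  expect_equal(g2$truth$onset_pct, g$truth$onset_pct)
  expect_false(isTRUE(all.equal(g2$channel$values, g$channel$values)))
})

test_that("zero-amplitude muscles yield pure noise and no main burst", {
  spec <- cohort_spec(n_horses = 1, strides_per_lead = 4, seed = 5)
  spec$burst_specs$amp_scale[] <- 0
  kin <- generate_kinematics(spec, 1, "left")
  g <- generate_semg(spec, kin$truth, "triceps")
  expect_lt(max(abs(g$truth$arv_true)), 1e-12)
  b <- detect_bursts(preprocess_emg(g$channel), kin$truth$strides, 0.59)
  expect_false(any(b$is_main) && any(b$duration_pct > 30))
})

test_that("true ARV is recovered from the noisy channel within 5%", {
  spec <- cohort_spec(n_horses = 1, strides_per_lead = 5, seed = 30)
  kin <- generate_kinematics(spec, 1, "left")
  st <- kin$truth$strides
  for (m in c("gluteal", "triceps")) {
    g <- generate_semg(spec, kin$truth, m)
    rect <- preprocess_emg(g$channel)
    for (k in seq_len(nrow(st))) {
      arv <- stride_arv(rect$values, rect$time,
                        c(st$start_s[k], st$end_s[k]))
      expect_lt(abs(arv - g$truth$arv_true[k]), 0.05 * g$truth$arv_true[k])
    }
  }
})

test_that("cohorts on disk are deterministic and refuse accidental overwrite", {
  spec <- cohort_spec(n_horses = 1, strides_per_lead = 3, seed = 42)
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  generate_cohort(spec, d1, force = TRUE)
  expect_error(generate_cohort(spec, d1), "force")
  generate_cohort(spec, d2, force = TRUE)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  man <- read_manifest(file.path(d1, "manifest.yaml"))
  expect_equal(length(man$trials), 2)
  gt <- read_ground_truth(d1)
  expect_equal(length(gt), 2)
})

test_that("the default cohort matches the scale of a ridden study", {
  spec <- cohort_spec()
  expect_equal(spec$n_horses, 10)
  total_per_lead <- spec$n_horses * spec$strides_per_lead
  expect_gte(total_per_lead, 55)
  expect_lte(total_per_lead, 80)
})
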