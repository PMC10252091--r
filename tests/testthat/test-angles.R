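test_that("a planar two-segment bend is recovered exactly", {
  m <- two_segment_markers(30)
  ang <- compute_joint_angles(m, two_segment_model())
  expect_equal(ang$bend$values, rep(30, 5), tolerance = 1e-9)
  m2 <- two_segment_markers(-17.5)
  ang2 <- compute_joint_angles(m2, two_segment_model())
  expect_equal(ang2$bend$values, rep(-17.5, 5), tolerance = 1e-9)
  # per-joint sign flips the convention
  ang3 <- compute_joint_angles(m, two_segment_model(sign = -1))
  expect_equal(ang3$bend$values, rep(-30, 5), tolerance = 1e-9)
})

test_that("degenerate segments are rejected with the segment named", {
  m <- two_segment_markers(10)
  m$coords$mid <- m$coords$prox                # zero-length upper segment
  expect_error(compute_joint_angles(m, two_segment_model()), "upper")
})

test_that("static normalization is exact, idempotent and invertible", {
  s <- joint_angle_series("carpus", c(95, 96, 94), 232)
  n1 <- normalize_to_static(s, 90)
  expect_equal(n1$values, c(5, 6, 4))
  expect_true(n1$normalized)
  expect_equal(normalize_to_static(s, 0)$values, s$values)
  # series equal to the static angle maps to zero
  expect_equal(normalize_to_static(
    joint_angle_series("carpus", rep(90, 3), 232), 90)$values, rep(0, 3))
  # invertible
  expect_equal(n1$values + 90, s$values)
})

test_that("a static trial normalized to itself gives all-zero curves", {
  m <- two_segment_markers(30, n = 20)
  ang <- compute_joint_angles(m, two_segment_model(), static = m)
  expect_lt(max(abs(ang$bend$values)), 1e-9)
  expect_true(ang$bend$normalized)
})

test_that("angular velocity matches closed forms", {
  rate <- 232
  t <- seq(0, 2, by = 1 / rate)
  expect_equal(angular_velocity(
    joint_angle_series("j", rep(45, 100), rate))$values, rep(0, 100))
  ramp <- angular_velocity(joint_angle_series("j", 10 * t, rate))
  expect_equal(ramp$values[2:(length(t) - 1)],
               rep(10, length(t) - 2), tolerance = 1e-6)
  A <- 20; f <- 3
  vel <- angular_velocity(joint_angle_series("j", A * sin(2 * pi * f * t),
                                             rate))
  expect_equal(max(abs(vel$values)), 2 * pi * f * A, tolerance = 5e-3)
  expect_identical(vel$unit, "deg_s")
})

test_that("pro-retraction angle is signed, zero at vertical, antisymmetric", {
  expect_equal(compute_proretraction(proret_markers(0), "fore")$values,
               rep(0, 4), tolerance = 1e-9)
  expect_equal(compute_proretraction(proret_markers(15), "fore")$values,
               rep(15, 4), tolerance = 1e-9)
  expect_equal(compute_proretraction(proret_markers(-15), "fore")$values,
               rep(-15, 4), tolerance = 1e-9)
  expect_equal(compute_proretraction(proret_markers(8, "hind"), "hind")$values,
               rep(8, 4), tolerance = 1e-9)
  m <- proret_markers(5)
  m$coords$fore_hoof <- NULL
  expect_error(compute_proretraction(m, "fore"), "fore_hoof")
})

test_that("joint angles recovered from synthetic markers match the truth", {
  spec <- cohort_spec(n_horses = 2, strides_per_lead = 4, seed = 21)
  kin <- generate_kinematics(spec, 1, "left")
  mf <- lowpass_kinematics(kin$markers, 12)
  static <- lowpass_kinematics(generate_static_trial(spec, 1), 12)
  ang <- compute_joint_angles(mf, static = static)
  base <- equigait:::joint_curve_basis()
  i <- mf$time > 0.2 & mf$time < max(mf$time) - 0.2
  for (j in base$joint) {
    tru <- kin$truth$angles_true[, j] - base$static[base$joint == j]
    rmse <- sqrt(mean((tru[i] - ang[[j]]$values[i])^2))
    expect_lt(rmse, 0.5)
  }
})

test_that("filtering and angle computation nearly commute on smooth motion", {
  spec <- cohort_spec(n_horses = 2, strides_per_lead = 3, seed = 8)
  kin <- generate_kinematics(spec, 2, "right")
  a_filt_first <- compute_joint_angles(lowpass_kinematics(kin$markers, 12))
  a_raw <- compute_joint_angles(kin$markers)
  i <- kin$markers$time > 0.2 & kin$markers$time < max(kin$markers$time) - 0.2
  for (j in c("carpus", "tarsus", "MCPJ")) {
    filt_after <- butter_zero_phase(a_raw[[j]]$values, 12, 232, "low")
    expect_lt(max(abs(a_filt_first[[j]]$values[i] - filt_after[i])), 0.2)
  }
})
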