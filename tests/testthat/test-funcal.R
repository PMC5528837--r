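test_that("the dominant rotation axis is recovered from angular velocity", {
  t <- seq(0, 6, by = 1 / 250)
  w <- rad(40) * sin(2 * pi * t / 3)
  gz <- cbind(0 * w, 0 * w, w)
  expect_equal(estimate_rotation_axis(gz, ref_axis = c(0, 0, 1)), c(0, 0, 1),
               tolerance = 1e-6)
  # oblique axis with an asymmetric rate profile: mean-projection sign rule
  ax <- c(1, 1, 0) / sqrt(2)
  w2 <- rad(40) * (sin(2 * pi * t / 3) + 0.3)
  g2 <- outer(w2, ax)
  got <- estimate_rotation_axis(g2)
  expect_lt(deg(acos(min(1, abs(sum(got * ax))))), 1e-6)
  expect_gt(sum(got * ax), 0)
  # flipped profile flips the reported sign
  got_neg <- estimate_rotation_axis(-g2)
  expect_lt(max(abs(got_neg + ax)), 1e-6)
  # noise moves the axis by less than a degree
  set.seed(51)
  g3 <- gz + matrix(stats::rnorm(length(gz), sd = rad(0.2)), ncol = 3L)
  got3 <- estimate_rotation_axis(g3, ref_axis = c(0, 0, 1))
  expect_lt(deg(acos(min(1, abs(got3[3L])))), 1)
  expect_error(estimate_rotation_axis(gz * 0.01), "insufficient rotation")
})

test_that("the gravity axis is the mean acceleration direction", {
  n <- 500L
  a_up <- matrix(rep(c(0, 9.81, 0), n), n, 3L, byrow = TRUE)
  expect_equal(estimate_gravity_axis(a_up), c(0, 1, 0), tolerance = 1e-12)
  # ski-boot stance: sensor pitched 17 degrees
  g17 <- quat_rotate(quat_from_axis_angle(c(0, 0, 1), rad(-17)), c(0, 9.81, 0))
  a17 <- matrix(rep(g17, n), n, 3L, byrow = TRUE)
  got <- estimate_gravity_axis(a17)
  expect_equal(deg(acos(sum(got * c(0, 1, 0)))), 17, tolerance = 1e-9)
  # white noise: axis within 0.2 degrees at SD 0.05 m/s^2
  set.seed(52)
  noisy <- a_up + matrix(stats::rnorm(3L * n, sd = 0.05), n, 3L)
  expect_lt(deg(acos(min(1, sum(estimate_gravity_axis(noisy) * c(0, 1, 0))))), 0.2)
  expect_error(estimate_gravity_axis(a_up * 0.5), "contamination")
})

test_that("trunk calibration recovers identity and injected misalignments", {
  cs <- calibration_sim()
  mv <- cs$cm$movements
  cal <- calibrate_trunk(mv$squats$lower_back, mv$trunk_rotations$lower_back,
                         mv$upright$lower_back)
  expect_lt(deg(quat_angle(cal$q)), 0.1)
  expect_lt(cal$diagnostics$vertical_axis_residual_deg, 0.5)
  # known misalignment injected through the simulator
  mnt <- quat_from_axis_angle(c(1, 2, -1) / sqrt(6), rad(14))
  chain <- ski_chain(mountings = list(lower_back = mnt))
  cm2 <- simulate_calibration_movements(chain, noise = NULL, rate = 250)
  cal2 <- calibrate_trunk(cm2$movements$squats$lower_back,
                          cm2$movements$trunk_rotations$lower_back,
                          cm2$movements$upright$lower_back)
  expect_lt(quat_angle_between(cal2$q, mnt), 1)
})

test_that("trunk calibration rejects near-collinear axes", {
  n <- 1500L
  t <- seq(0, by = 1 / 250, length.out = n)
  w <- rad(40) * sin(2 * pi * t / 3)
  vert_rot <- imu_stream(t, matrix(rep(c(0, 9.81, 0), n), n, 3L, byrow = TRUE),
                         cbind(0 * w, w, 0 * w))
  expect_error(calibrate_trunk(vert_rot, vert_rot, vert_rot), "collinear")
})

test_that("thigh calibration resolves the axial rotation by hip-acceleration matching", {
  cs <- calibration_sim()
  mv <- cs$cm$movements
  cal_lb <- calibrate_trunk(mv$squats$lower_back, mv$trunk_rotations$lower_back,
                            mv$upright$lower_back)
  cal <- calibrate_thigh(mv$squats$thigh_l, mv$upright$thigh_l,
                         mv$squats$lower_back, cal_lb)
  expect_lt(deg(quat_angle(cal$q)), 0.5)
  # injected 15 degree axial misalignment is recovered
  mnt <- quat_from_axis_angle(c(0, 1, 0), rad(15))
  chain <- ski_chain(mountings = list(thigh_l = mnt))
  cm2 <- simulate_calibration_movements(chain, noise = NULL, rate = 250)
  cal_lb2 <- calibrate_trunk(cm2$movements$squats$lower_back,
                             cm2$movements$trunk_rotations$lower_back,
                             cm2$movements$upright$lower_back)
  cal2 <- calibrate_thigh(cm2$movements$squats$thigh_l,
                          cm2$movements$upright$thigh_l,
                          cm2$movements$squats$lower_back, cal_lb2)
  expect_lt(quat_angle_between(cal2$q, mnt), 1.5)
  # the optimizer's minimum agrees with a 1-degree grid search
  grid <- seq(-30, 30, by = 1)
  gv <- vapply(grid, cal2$diagnostics$objective, numeric(1L))
  expect_lte(abs(grid[which.min(gv)] - cal2$diagnostics$theta_deg), 1)
})

test_that("shank calibration uses the ab/adduction axis and start-of-movement gravity", {
  cs <- calibration_sim()
  mv <- cs$cm$movements
  cal <- calibrate_shank(mv$hip_abduction_left$shank_l)
  expect_lt(deg(quat_angle(cal$q)), 0.5)
  mnt <- quat_from_axis_angle(c(2, -1, 1) / sqrt(6), rad(18))
  chain <- ski_chain(mountings = list(shank_r = mnt))
  cm2 <- simulate_calibration_movements(chain, noise = NULL, rate = 250)
  cal2 <- calibrate_shank(cm2$movements$hip_abduction_right$shank_r)
  expect_lt(quat_angle_between(cal2$q, mnt), 1)
  # left/right calibrations of a symmetric subject give mirror-consistent axes
  cal_l <- calibrate_shank(cs$cm$movements$hip_abduction_left$shank_l)
  cal_r <- calibrate_shank(cs$cm$movements$hip_abduction_right$shank_r)
  expect_lt(quat_angle_between(cal_l$q, cal_r$q), 1)
})

test_that("lower-limb refinement enforces the three constraints", {
  cs <- calibration_sim()
  cals <- calibrate_all(cs$cm$movements, refine = FALSE)
  # constraints already satisfied: refinement is a no-op
  ref <- refine_lower_limb(cals, cs$cm$movements)
  expect_true(all(ref$correction_deg < 0.1))
  # inject a 5 degree knee-flexion (pitch) error into the thigh calibration
  bad <- cals
  bad$thigh_l$q <- quat_multiply(quat_from_axis_angle(c(0, 0, 1), rad(5)),
                                 bad$thigh_l$q)
  ref2 <- refine_lower_limb(bad, cs$cm$movements)
  expect_gt(abs(ref2$report$before_deg[ref2$report$constraint == "knee_flexion_left"]), 4)
  expect_lt(abs(ref2$report$after_deg[ref2$report$constraint == "knee_flexion_left"]), 0.5)
  # asymmetric left/right misalignment: symmetry residual reduced below 1 degree
  asym <- cals
  asym$shank_l$q <- quat_multiply(quat_from_axis_angle(c(1, 0, 0), rad(6)),
                                  asym$shank_l$q)
  ref3 <- refine_lower_limb(asym, cs$cm$movements)
  expect_gt(ref3$report$before_deg[ref3$report$constraint == "symmetry_shank"], 4)
  expect_lt(ref3$report$after_deg[ref3$report$constraint == "symmetry_shank"], 1)
  # gross corrections are flagged as movement mis-execution
  gross <- cals
  gross$thigh_l$q <- quat_multiply(quat_from_axis_angle(c(0, 0, 1), rad(40)),
                                   gross$thigh_l$q)
  expect_error(refine_lower_limb(gross, cs$cm$movements), "mis-executed")
})

test_that("dispersion chi matches its closed forms and brute-force formula", {
  q <- quat_from_axis_angle(c(0, 1, 0), 0.3)
  expect_equal(dispersion_chi(rbind(q, q, q)), 0, tolerance = 1e-9)
  # two quaternions at +/- theta about a common axis: each Delta = theta,
  # chi = sqrt(2 theta^2 / 1) = theta * sqrt(2)
  theta <- rad(4)
  qa <- quat_from_axis_angle(c(1, 0, 0), theta)
  qb <- quat_from_axis_angle(c(1, 0, 0), -theta)
  expect_equal(dispersion_chi(rbind(qa, qb)), deg(theta) * sqrt(2),
               tolerance = 1e-9)
  expect_error(dispersion_chi(matrix(quat_identity(), 1, 4)), "at least 2")
})

test_that("dispersion chi is invariant to a common left-multiplied rotation", {
  set.seed(53)
  qs <- t(vapply(1:5, function(i) {
    quat_multiply(quat_from_axis_angle(random_unit_vec(), rad(stats::runif(1, 0, 4))),
                  quat_from_axis_angle(c(0, 1, 0), 0.5))
  }, numeric(4L)))
  chi0 <- dispersion_chi(qs)
  r <- quat_from_axis_angle(random_unit_vec(), 1.1)
  qs_rot <- t(apply(qs, 1L, function(q) quat_multiply(r, q)))
  expect_equal(dispersion_chi(qs_rot), chi0, tolerance = 1e-9)
})
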