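test_that("an all-zero script leaves the chain identically oriented", {
  chain <- ski_chain()
  t <- seq(0, 2, by = 0.01)
  n <- length(t)
  zero <- matrix(0, n, 3L)
  joints <- stats::setNames(rep(list(zero), length(chain$joints)),
                            names(chain$joints))
  script <- skimu:::.motion_script(t, 100, matrix(0, n, 3L),
                                   matrix(rep(quat_identity(), n), n, 4L,
                                          byrow = TRUE), joints)
  sim <- simulate_trial(chain, script)
  for (nm in names(chain$segments)) {
    expect_lt(max(quat_angle(sim$q[[nm]])), 1e-12)
  }
  traces <- truth_traces(sim, chain)
  ang <- trial_joint_angles(traces, chain)
  for (jn in names(ang)) expect_lt(max(abs(unlist(ang[[jn]][, 2:4]))), 1e-9)
})

test_that("a missing joint trajectory is rejected", {
  chain <- ski_chain()
  script <- ski_motion_script(duration = 2, rate = 100)
  script$joints$knee_l <- NULL
  expect_error(simulate_trial(chain, script), "knee_l")
})

test_that("a pure knee-flexion sinusoid is recovered exactly", {
  chain <- ski_chain()
  t <- seq(0, 6, by = 1 / 250)
  n <- length(t)
  zero <- matrix(0, n, 3L)
  flex <- 30 * sin(2 * pi * t / 3)
  joints <- stats::setNames(rep(list(zero), length(chain$joints)),
                            names(chain$joints))
  joints$knee_l <- cbind(flex, 0, 0)
  script <- skimu:::.motion_script(t, 250, matrix(0, n, 3L),
                                   matrix(rep(quat_identity(), n), n, 4L,
                                          byrow = TRUE), joints)
  sim <- simulate_trial(chain, script)
  got <- grood_suntay(sim$q$thigh_l, sim$q$shank_l)
  expect_lt(max(abs(got$flexion - flex)), 1e-6)
})

test_that("the skiing script produces turn cycles at the scripted period", {
  tr <- small_trial()
  lb <- tr$streams$lower_back
  gyro_sm <- skimu:::lowpass_cols(lb$gyro, lb$rate, 2)
  omega_g <- quat_rotate(tr$sim$q$lower_back, gyro_sm)
  starts <- detect_cycles(omega_g[, 1L], lb$rate)
  # the first inter-peak interval falls in the ramp from standstill; the
  # steady-state periods match the scripted turn period to within a sample
  periods <- diff(starts)[-1L] / lb$rate
  expect_true(all(abs(periods - tr$sim$script$turn_period) <= 1 / lb$rate + 1e-9))
})

test_that("synthesized IMU signals match static and constant-rate closed forms", {
  # static pitched segment: accel reads gravity in the sensor frame, gyro 0
  t <- seq(0, 2, by = 0.01)
  n <- length(t)
  q <- quat_from_axis_angle(c(0, 0, 1), rad(-17))
  qm <- matrix(rep(q, n), n, 4L, byrow = TRUE)
  pos <- matrix(rep(c(0, 1, 0), n), n, 3L, byrow = TRUE)
  st <- synthesize_imu(t, qm, pos, noise = NULL)
  expect_lt(max(skimu:::vec3_norm(st$gyro)), 1e-9)
  want <- quat_rotate(quat_conjugate(q), c(0, 9.81, 0))
  expect_lt(max(skimu:::vec3_norm(sweep(st$accel, 2L, want))), 1e-9)

  # constant rotation rate about a fixed axis
  w <- rad(90)
  qm2 <- t(vapply(t, function(ti) quat_from_axis_angle(c(0, 0, 1), w * ti),
                  numeric(4L)))
  st2 <- synthesize_imu(t, qm2, pos, noise = NULL)
  inner <- 2:(n - 1L)
  expect_lt(max(abs(skimu:::vec3_norm(st2$gyro[inner, ]) - w)), 1e-6)
  expect_error(synthesize_imu(t^1.01, qm, pos), "non-uniform")
})

test_that("accelerations of adjacent sensors agree when translated to their joint", {
  tr <- small_trial()
  j <- tr$chain$joints$knee_l
  cd <- function(g, rate) {
    n <- nrow(g); d <- matrix(0, n, 3L)
    d[2:(n - 1L), ] <- (g[3:n, ] - g[1:(n - 2L), ]) * (rate / 2)
    d[1L, ] <- d[2L, ]; d[n, ] <- d[n - 1L, ]
    d
  }
  th <- tr$streams$thigh_l; sh <- tr$streams$shank_l
  a_th <- translate_acceleration(th$accel, th$gyro, cd(th$gyro, th$rate), j$r_p)
  a_sh <- translate_acceleration(sh$accel, sh$gyro, cd(sh$gyro, sh$rate), j$r_d)
  d <- skimu:::vec3_norm(quat_rotate(tr$sim$q$thigh_l, a_th) -
                           quat_rotate(tr$sim$q$shank_l, a_sh))
  n <- length(d)
  expect_lt(max(d[5:(n - 5L)]), 1e-4)
})

test_that("noise-free strap-down integration reproduces ground truth", {
  tr <- small_trial()
  st <- tr$streams$shank_l
  trace <- strapdown_integrate(st, tr$sim$q$shank_l[1L, ])
  err <- quat_angle(quat_multiply(trace$q, quat_conjugate(tr$sim$q$shank_l)))
  expect_lt(max(deg(err)), 0.1)
})

test_that("injected gyro bias is recovered from the upright stance", {
  chain <- ski_chain()
  nm <- noise_model(gyro_bias_deg_s = c(0.30, -0.10, 0.20),
                    gyro_noise_sd_deg_s = 0.2, accel_noise_sd = 0.05, seed = 31)
  up <- upright_script(rate = 250)
  sim <- simulate_trial(chain, up)
  streams <- synthesize_trial_imu(sim, chain, noise = nm,
                                  segments = "lower_back")
  off <- estimate_gyro_offset(streams$lower_back)
  # mean of N white-noise samples has SD sigma/sqrt(N)
  n <- length(streams$lower_back$t)
  floor3 <- 3 * rad(0.2) / sqrt(n)
  expect_lt(max(abs(off - rad(c(0.30, -0.10, 0.20)))), floor3)
})

test_that("synthesis is deterministic for a fixed seed", {
  chain <- ski_chain()
  script <- ski_motion_script(duration = 4, rate = 100)
  sim <- simulate_trial(chain, script)
  nm <- noise_model(seed = 7)
  s1 <- synthesize_trial_imu(sim, chain, nm, segments = "shank_l")
  s2 <- synthesize_trial_imu(sim, chain, nm, segments = "shank_l")
  expect_identical(s1$shank_l$gyro, s2$shank_l$gyro)
  expect_identical(s1$shank_l$accel, s2$shank_l$accel)
  # different sensors draw independent noise
  s3 <- synthesize_trial_imu(sim, chain, nm, segments = c("shank_l", "thigh_l"))
  expect_gt(max(abs(s3$shank_l$accel - s3$thigh_l$accel)), 1e-3)
})

test_that("calibration movements satisfy their hypotheses in the ideal case", {
  cs <- calibration_sim()
  mv <- cs$cm$movements
  # squat rotates the thigh about its medio-lateral axis
  ax <- estimate_rotation_axis(mv$squats$thigh_l, ref_axis = c(0, 0, 1))
  expect_lt(deg(acos(min(1, abs(ax[3L])))), 1e-3)
  # trunk rotations are about the vertical axis of the upright lower back
  axv <- estimate_rotation_axis(mv$trunk_rotations$lower_back, ref_axis = c(0, 1, 0))
  expect_lt(deg(acos(min(1, abs(axv[2L])))), 1e-3)
  # ab/adduction rotates the shank about its anterior-posterior axis
  axa <- estimate_rotation_axis(mv$hip_abduction_left$shank_l, ref_axis = c(1, 0, 0))
  expect_lt(deg(acos(min(1, abs(axa[1L])))), 1e-3)
  # upright stance is quasi-static
  expect_lt(max(skimu:::vec3_norm(mv$upright$shank_l$gyro)), rad(0.5))
})
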