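static_accel <- function(q, n = 500L) {
  g <- quat_rotate(quat_conjugate(q), c(0, 9.81, 0))
  matrix(rep(g, n), n, 3L, byrow = TRUE)
}

test_that("initial orientation takes inclination from gravity, azimuth zero", {
  expect_lt(deg(quat_angle(initial_orientation(static_accel(quat_identity())))), 1e-9)
  # pitched 17 degrees: recovered with zero azimuth
  q17 <- quat_from_axis_angle(c(0, 0, 1), rad(-17))
  got <- initial_orientation(static_accel(q17))
  expect_lt(quat_angle_between(got, q17), 1e-6)
  # segments with different true azimuths are both initialised to azimuth 0
  q_yaw <- quat_multiply(quat_from_axis_angle(c(0, 1, 0), rad(40)), q17)
  got2 <- initial_orientation(static_accel(q_yaw))
  expect_lt(quat_angle_between(got2, q17), 1e-6)
  # non-static window is rejected
  set.seed(61)
  moving <- static_accel(quat_identity()) +
    cbind(8 * sin(seq_len(500L)), 0, 0)
  expect_error(initial_orientation(moving), "non-static")
})

test_that("strap-down integration satisfies closed-form cases", {
  n <- 501L
  t <- seq(0, by = 1 / 500, length.out = n)
  zero <- matrix(0, n, 3L)
  st0 <- imu_stream(t, matrix(rep(c(0, 9.81, 0), n), n, 3L, byrow = TRUE), zero)
  q0 <- quat_from_axis_angle(c(1, 0, 0), 0.3)
  tr0 <- strapdown_integrate(st0, q0)
  expect_lt(max(apply(tr0$q, 1L, function(q) quat_angle_between(q, q0))), 1e-9)
  # constant 90 deg/s about body Z for 1 s
  stz <- imu_stream(t, matrix(rep(c(0, 9.81, 0), n), n, 3L, byrow = TRUE),
                    matrix(rep(c(0, 0, rad(90)), n), n, 3L, byrow = TRUE))
  trz <- strapdown_integrate(stz, quat_identity())
  expect_lt(quat_angle_between(trz$q[n, ], quat_from_axis_angle(c(0, 0, 1), pi / 2)),
            1e-6)
  stz$gyro[5L, 2L] <- NaN
  expect_error(strapdown_integrate(stz, quat_identity()), "NaN")
})

test_that("rigid-body acceleration translation has its closed forms", {
  a <- c(1, 2, 3)
  expect_equal(translate_acceleration(a, c(0, 0, 0), c(0, 0, 0), c(0.1, 0.2, 0.3)), a)
  expect_equal(translate_acceleration(a, c(1, 2, 3), c(4, 5, 6), c(0, 0, 0)), a)
  # constant spin about Z with r along X: pure centripetal -|w|^2 r
  w <- 3
  got <- translate_acceleration(c(0, 0, 0), c(0, 0, w), c(0, 0, 0), c(0.5, 0, 0))
  expect_equal(got, c(-w^2 * 0.5, 0, 0), tolerance = 1e-12)
})

test_that("the valid-sample mask implements the magnitude and 20% rules", {
  unit <- function(m) c(m, 0, 0)
  # both magnitudes 7 > 6, relative difference 0: valid
  expect_true(valid_sample_mask(rbind(unit(7)), rbind(unit(7))))
  # distal magnitude 5 < 6: invalid regardless of the proximal
  expect_false(valid_sample_mask(rbind(unit(5)), rbind(unit(100))))
  # magnitudes 10 vs 8: relative difference 2/9 > 0.2: invalid
  expect_false(valid_sample_mask(rbind(unit(10)), rbind(unit(8))))
  # just inside the boundary: 10 vs 8.2 gives 1.8/9.1 < 0.2: valid
  expect_true(valid_sample_mask(rbind(unit(10)), rbind(unit(8.2))))
  expect_error(valid_sample_mask(matrix(1, 2, 3), matrix(1, 3, 3)), "length")
})

test_that("cycle detection finds scripted turn starts and rejects degenerate input", {
  rate <- 200
  t <- seq(0, 24, by = 1 / rate)
  x <- sin(2 * pi * t / 4)
  starts <- detect_cycles(x, rate)
  expect_true(all(abs(diff(starts) / rate - 4) <= 1 / rate + 1e-9))
  expect_error(detect_cycles(rep(1, 5000), rate), "maxima|constant")
  # jittered periods: the count matches the scripted cycle count
  set.seed(62)
  phase <- cumsum(2 * pi / (4 + 0.3 * sin(seq_along(t) / 800)) / rate)
  xj <- sin(phase)
  nj <- length(detect_cycles(xj, rate))
  expect_equal(nj, floor(max(phase) / (2 * pi)) + 1L, tolerance = 1L)
})

test_that("drift estimation recovers constructed orientation errors", {
  tr <- small_trial()
  chain <- tr$chain
  j <- chain$joints$knee_l
  th <- tr$streams$thigh_l; sh <- tr$streams$shank_l
  trace_th <- orientation_trace(tr$sim$t, tr$sim$q$thigh_l, "thigh_l")
  trace_sh <- orientation_trace(tr$sim$t, tr$sim$q$shank_l, "shank_l")
  od_th <- gyro_derivative(th$gyro, th$rate)
  od_sh <- gyro_derivative(sh$gyro, sh$rate)
  ap <- joint_acceleration_global(trace_th, th, j$r_p, od_th)
  ad <- joint_acceleration_global(trace_sh, sh, j$r_d, od_sh)
  gyro_sm <- skimu:::lowpass_cols(th$gyro, th$rate, 2)
  cyc <- detect_cycles(quat_rotate(trace_th$q, gyro_sm)[, 1L], th$rate)

  # drift-free: all mismatch angles small, window means near identity
  est0 <- estimate_drift(ad, ap, cyc)
  expect_lt(max(est0$beta_deg, na.rm = TRUE), 0.5)
  expect_lt(max(est0$windows$angle_deg), 0.1)

  # constant 5 degree error injected on the distal trace
  e5 <- quat_from_axis_angle(c(0, 0, 1), rad(5))
  bad <- quat_multiply(matrix(e5, 1, 4)[rep(1, nrow(trace_sh$q)), ], trace_sh$q)
  ad5 <- joint_acceleration_global(orientation_trace(tr$sim$t, bad, "shank_l"),
                                   sh, j$r_d, od_sh)
  est5 <- estimate_drift(ad5, ap, cyc)
  mid <- ceiling(nrow(est5$windows) / 2)
  expect_lt(abs(est5$windows$angle_deg[mid] - 5), 0.5)
  # and the correction undoes it
  fixed <- correct_orientations(orientation_trace(tr$sim$t, bad, "shank_l"), est5)
  err <- quat_angle(quat_multiply(fixed$q, quat_conjugate(trace_sh$q)))
  inner <- seq(cyc[1L], cyc[length(cyc)])
  expect_lt(stats::median(deg(err[inner])), 1)
})

test_that("drift estimation is frame-consistent under a common global rotation", {
  tr <- small_trial()
  j <- tr$chain$joints$knee_l
  th <- tr$streams$thigh_l; sh <- tr$streams$shank_l
  trace_th <- orientation_trace(tr$sim$t, tr$sim$q$thigh_l, "thigh_l")
  od_th <- gyro_derivative(th$gyro, th$rate)
  od_sh <- gyro_derivative(sh$gyro, sh$rate)
  ap <- joint_acceleration_global(trace_th, th, j$r_p, od_th)
  e5 <- quat_from_axis_angle(c(1, 1, 1) / sqrt(3), rad(6))
  bad <- quat_multiply(matrix(e5, 1, 4)[rep(1, nrow(tr$sim$q$shank_l)), ],
                       tr$sim$q$shank_l)
  ad <- joint_acceleration_global(orientation_trace(tr$sim$t, bad, "s"), sh,
                                  j$r_d, od_sh)
  gyro_sm <- skimu:::lowpass_cols(th$gyro, th$rate, 2)
  cyc <- detect_cycles(quat_rotate(trace_th$q, gyro_sm)[, 1L], th$rate)
  est <- estimate_drift(ad, ap, cyc)
  r <- quat_from_axis_angle(c(0.2, 1, -0.4) / sqrt(1.2), 0.8)
  est_rot <- estimate_drift(quat_rotate(r, ad), quat_rotate(r, ap), cyc)
  k <- ceiling(nrow(est$windows) / 2)
  q1 <- unlist(est$windows[k, c("qw", "qx", "qy", "qz")])
  q2 <- unlist(est_rot$windows[k, c("qw", "qx", "qy", "qz")])
  conj <- quat_multiply(quat_multiply(r, q1), quat_conjugate(r))
  expect_lt(quat_angle_between(conj, q2), 1e-6)
})

test_that("the azimuth pass isolates heading error and needs horizontal signal", {
  tr <- small_trial()
  j <- tr$chain$joints$knee_l
  th <- tr$streams$thigh_l; sh <- tr$streams$shank_l
  trace_th <- orientation_trace(tr$sim$t, tr$sim$q$thigh_l, "thigh_l")
  od_th <- gyro_derivative(th$gyro, th$rate)
  od_sh <- gyro_derivative(sh$gyro, sh$rate)
  ap <- joint_acceleration_global(trace_th, th, j$r_p, od_th)
  gyro_sm <- skimu:::lowpass_cols(th$gyro, th$rate, 2)
  cyc <- detect_cycles(quat_rotate(trace_th$q, gyro_sm)[, 1L], th$rate)
  # pure 10 degree azimuth offset on the distal trace
  e10 <- quat_from_axis_angle(c(0, 1, 0), rad(10))
  bad <- quat_multiply(matrix(e10, 1, 4)[rep(1, nrow(tr$sim$q$shank_l)), ],
                       tr$sim$q$shank_l)
  ad <- joint_acceleration_global(orientation_trace(tr$sim$t, bad, "s"), sh,
                                  j$r_d, od_sh)
  est <- estimate_drift(ad, ap, cyc, azimuth = TRUE)
  k <- ceiling(nrow(est$windows) / 2)
  qk <- unlist(est$windows[k, c("qw", "qx", "qy", "qz")])
  # the estimate is the correction that undoes the injected offset
  expect_lt(quat_angle_between(qk, quat_conjugate(e10)), 1)
  # zero horizontal acceleration: no valid samples
  n <- nrow(ap)
  vert <- cbind(0, 9.81 + sin(seq_len(n) / 50), 0)
  expect_error(estimate_drift(vert, vert, cyc, azimuth = TRUE), "no valid samples")
  # a vertical-only difference is removed by the vertical zeroing
  vert2 <- cbind(ap[, 1L], ap[, 2L] + 2, ap[, 3L])
  est2 <- estimate_drift(vert2, ap, cyc, azimuth = TRUE)
  expect_lt(max(est2$windows$angle_deg), 0.5)
})

test_that("corrected traces stay unit-norm, continuous, and identity is a no-op", {
  tr <- small_trial()
  trace <- orientation_trace(tr$sim$t, tr$sim$q$shank_l, "shank_l")
  n <- nrow(trace$q)
  wins <- data.frame(start = c(1L, floor(n / 2) + 1L),
                     end = c(floor(n / 2), n),
                     mid = c(floor(n / 4), floor(3 * n / 4)))
  idq <- quat_identity()
  wins$qw <- idq[1L]; wins$qx <- idq[2L]; wins$qy <- idq[3L]; wins$qz <- idq[4L]
  noop <- correct_orientations(trace, structure(list(windows = wins),
                                                class = "drift_estimate"))
  expect_equal(noop$q, trace$q, tolerance = 1e-12)
  # single-window 5 degree azimuth shift moves every sample's heading
  w1 <- wins[1L, ]
  w1$end <- n; w1$mid <- floor(n / 2)
  e5 <- quat_from_axis_angle(c(0, 1, 0), rad(5))
  w1$qw <- e5[1L]; w1$qx <- e5[2L]; w1$qy <- e5[3L]; w1$qz <- e5[4L]
  shifted <- correct_orientations(trace, structure(list(windows = w1),
                                                   class = "drift_estimate"))
  errs <- quat_multiply(shifted$q, quat_conjugate(trace$q))
  expect_lt(max(abs(deg(quat_angle(errs)) - 5)), 1e-6)
  # continuity: inter-sample angle bounded by rate * dt plus correction slope
  dqa <- quat_angle(quat_multiply(shifted$q[-1L, ], quat_conjugate(shifted$q[-n, ])))
  wmax <- max(skimu:::vec3_norm(tr$streams$shank_l$gyro))
  expect_lt(max(dqa), wmax / tr$streams$shank_l$rate + rad(0.1))
})

test_that("injected gyro bias makes drift grow monotonically across windows", {
  tr <- small_trial()
  chain <- tr$chain
  j <- chain$joints$knee_l
  noise <- noise_model(gyro_noise_sd_deg_s = 0, accel_noise_sd = 0, seed = NULL)
  sts <- synthesize_trial_imu(tr$sim, chain, noise,
                              segments = c("thigh_l", "shank_l"))
  tr_th <- strapdown_integrate(sts$thigh_l, tr$sim$q$thigh_l[1L, ])
  tr_sh <- strapdown_integrate(sts$shank_l, tr$sim$q$shank_l[1L, ])
  od_th <- gyro_derivative(sts$thigh_l$gyro, sts$thigh_l$rate)
  od_sh <- gyro_derivative(sts$shank_l$gyro, sts$shank_l$rate)
  ap <- joint_acceleration_global(tr_th, sts$thigh_l, j$r_p, od_th)
  ad <- joint_acceleration_global(tr_sh, sts$shank_l, j$r_d, od_sh)
  gyro_sm <- skimu:::lowpass_cols(sts$thigh_l$gyro, sts$thigh_l$rate, 2)
  cyc <- detect_cycles(quat_rotate(tr_th$q, gyro_sm)[, 1L], sts$thigh_l$rate)
  est <- estimate_drift(ad, ap, cyc)
  a <- est$windows$angle_deg
  expect_gt(a[length(a)], a[1L])
  expect_gt(stats::cor(seq_along(a), a, method = "spearman"), 0.9)
})
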