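#' Rigid-body kinematic-chain simulation of skiing and calibration movements
#'
#' The simulator produces ground-truth segment orientations, sensor
#' positions, and synthetic IMU signals for a six-segment chain (lower back
#' as root; sternum; left/right thighs and shanks) connected by the trunk,
#' hip and knee joints. It stands in for raw field recordings: it emulates
#' cyclic carpet-skiing turns (~4 s per left+right turn cycle, 120 s trials),
#' the four functional-calibration movements, gyroscope bias and white
#' noise, and sensor mounting misalignment. Soft-tissue artefact is not
#' modelled: segments are perfectly rigid.
#'
#' All scripted joint-angle trajectories are built from smooth sinusoids so
#' recovered angles are exactly comparable to the script. Gyroscope signals
#' are derived from the ground-truth orientations by central-difference
#' quaternion logarithms and accelerometers from central second differences
#' of the sensor positions plus gravity, keeping the simulator independent
#' of the strap-down integrator under test.
#'
#' @name synthetic
NULL

#' Default skiing kinematic chain
#'
#' Segment geometry with sensor-to-joint vectors in each segment's
#' anatomical frame (X anterior, Y superior, Z right; metres). The
#' sensor-to-hip-centre vectors are (0.05, -0.10, 0) m for the lower back
#' and (-0.05, 0.30, 0) m for the thigh; remaining offsets are realistic
#' sensor placements at mid-segment. Each segment carries a mounting
#' quaternion (sensor to anatomical frame; identity = perfectly aligned)
#' and a gyro-bias sign multiplier (default +1: every sensor receives the
#' noise model's bias vector as is; adjacent segments still drift apart in
#' their relative orientation because their postures differ).
#'
#' @param mountings optional named list of mounting quaternions overriding
#'   the identity default per segment.
#' @return a `chain_model` list with `segments` and `joints`.
#' @export
ski_chain <- function(mountings = NULL) {
  segs <- list(
    lower_back = list(bias_sign = +1),
    sternum    = list(bias_sign = +1),
    thigh_l    = list(bias_sign = +1),
    thigh_r    = list(bias_sign = +1),
    shank_l    = list(bias_sign = +1),
    shank_r    = list(bias_sign = +1)
  )
  for (nm in names(segs)) {
    segs[[nm]]$mounting <- quat_identity()
  }
  if (!is.null(mountings)) {
    for (nm in names(mountings)) {
      if (!nm %in% names(segs)) stop(sprintf("unknown segment '%s'", nm))
      segs[[nm]]$mounting <- quat_normalize(mountings[[nm]])
    }
  }
  joints <- list(
    trunk  = list(prox = "lower_back", dist = "sternum",
                  r_p = c(0.00, 0.12, 0.00), r_d = c(-0.08, -0.20, 0.00)),
    hip_l  = list(prox = "lower_back", dist = "thigh_l",
                  r_p = c(0.05, -0.10, 0.00), r_d = c(-0.05, 0.30, 0.00)),
    hip_r  = list(prox = "lower_back", dist = "thigh_r",
                  r_p = c(0.05, -0.10, 0.00), r_d = c(-0.05, 0.30, 0.00)),
    knee_l = list(prox = "thigh_l", dist = "shank_l",
                  r_p = c(-0.02, -0.18, 0.00), r_d = c(0.01, 0.20, 0.00)),
    knee_r = list(prox = "thigh_r", dist = "shank_r",
                  r_p = c(-0.02, -0.18, 0.00), r_d = c(0.01, 0.20, 0.00))
  )
  structure(list(segments = segs, joints = joints), class = "chain_model")
}

#' Sensor noise model
#'
#' Defaults reflect a consumer-grade MEMS IMU after coarse factory
#' calibration: constant gyroscope bias of 0.25 deg/s magnitude per axis
#' (sign pattern +,+,- ; with the default chain postures this accumulates
#' roughly 30 degrees of uncorrected knee azimuth drift over a 120 s
#' trial), 0.2 deg/s gyroscope white noise, 0.05 m/s^2 accelerometer white
#' noise.
#'
#' @param gyro_bias_deg_s constant gyro bias per axis, deg/s (3-vector or
#'   scalar).
#' @param gyro_noise_sd_deg_s gyro white-noise SD, deg/s.
#' @param accel_noise_sd accelerometer white-noise SD, m/s^2.
#' @param seed RNG seed; mandatory whenever any noise SD is positive.
#' @return a `noise_model` list (bias stored in rad/s).
#' @export
noise_model <- function(gyro_bias_deg_s = c(0.25, 0.25, -0.25),
                        gyro_noise_sd_deg_s = 0.2,
                        accel_noise_sd = 0.05,
                        seed = NULL) {
  if (gyro_noise_sd_deg_s < 0 || accel_noise_sd < 0) stop("noise SDs must be >= 0")
  if ((gyro_noise_sd_deg_s > 0 || accel_noise_sd > 0) && is.null(seed)) {
    stop("a seed is required when white noise is enabled")
  }
  structure(list(gyro_bias = deg2rad(rep_len(gyro_bias_deg_s, 3L)),
                 gyro_noise_sd = deg2rad(gyro_noise_sd_deg_s),
                 accel_noise_sd = accel_noise_sd,
                 seed = seed),
            class = "noise_model")
}

# Evaluate code with a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# C-infinity ramp (bump-function transition): every derivative vanishes at
# both ends, so scripted kinematics stay smooth to all orders and
# finite-difference consistency checks see no transition artefacts.
smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  f <- function(v) ifelse(v > 0, exp(-1 / pmax(v, 1e-12)), 0)
  a <- f(u); b <- f(1 - u)
  a / (a + b)
}

# Assemble a motion script structure. Joint angle matrices are degrees with
# columns flexion/abduction/rotation in the "zxy" joint convention.
.motion_script <- function(t, rate, root_pos, root_q, joints, turn_period = NA) {
  structure(list(t = t, rate = rate, duration = t[length(t)] - t[1L],
                 turn_period = turn_period,
                 root = list(pos = root_pos, q = root_q),
                 joints = joints),
            class = "motion_script")
}

.angles3 <- function(flexion, abduction, rotation, n) {
  cbind(flexion = rep_len(flexion, n), abduction = rep_len(abduction, n),
        rotation = rep_len(rotation, n))
}

# Root orientation from yaw (about global Y), pitch (about Z, forward lean
# negative), roll (about X), all degrees, applied in that order.
.root_quat <- function(yaw, pitch, roll, n) {
  yaw <- deg2rad(rep_len(yaw, n)); pitch <- deg2rad(rep_len(pitch, n))
  roll <- deg2rad(rep_len(roll, n))
  qy <- cbind(cos(yaw / 2), 0, sin(yaw / 2), 0)
  qz <- cbind(cos(pitch / 2), 0, 0, sin(pitch / 2))
  qx <- cbind(cos(roll / 2), sin(roll / 2), 0, 0)
  quat_normalize(.quat_mult_raw(.quat_mult_raw(qy, qz), qx))
}

#' Default skiing motion script
#'
#' Cyclic left/right turns with joint-angle amplitudes matching reference
#' ranges reported for indoor carpet skiing: knee flexion oscillating
#' 36.3-74.7 deg, hip flexion -67.2 to -24.8 deg, trunk flexion 3.7-16.6 deg
#' and trunk lateral/axial angles within about +/-7 deg. The whole body
#' yaws and rolls with the turn rhythm and the pelvis translates laterally
#' (+/-0.6 m) and vertically with the turn cycle, which provides the
#' horizontal joint accelerations that make azimuth drift observable. A
#' smooth 2 s ramp from standstill makes the trial start quasi-static so the
#' initial orientation can be taken from gravity.
#'
#' @param duration trial length, seconds (default 120).
#' @param rate sampling rate, Hz (default 500).
#' @param turn_period seconds per movement cycle = one left + one right turn
#'   (default 4).
#' @param ramp ramp-in time from standstill, seconds.
#' @return a `motion_script`.
#' @export
ski_motion_script <- function(duration = 120, rate = 500, turn_period = 4,
                              ramp = 2) {
  t <- seq(0, duration, by = 1 / rate)
  n <- length(t)
  e <- smoothstep(t / ramp)
  th <- 2 * pi * t / turn_period
  s1 <- e * sin(th); c1 <- e * cos(th)
  joints <- list(
    trunk  = .angles3(10.15 + 6.45 * s1, 6.3 * s1, 6.85 * c1, n),
    hip_l  = .angles3(-46 + 21.2 * s1, 10 * s1, 8 * s1, n),
    hip_r  = .angles3(-46 - 21.2 * s1, -10 * s1, -8 * s1, n),
    knee_l = .angles3(55.5 - 19.2 * s1, -4 * s1, 6 * s1, n),
    knee_r = .angles3(55.5 + 19.2 * s1, 4 * s1, -6 * s1, n)
  )
  pos <- cbind(0.15 * s1, 1.00 + 0.06 * e * (cos(2 * th) - 1), 0.60 * s1)
  q_root <- .root_quat(yaw = 15 * s1, pitch = -12 * e, roll = 10 * s1, n)
  .motion_script(t, rate, pos, q_root, joints, turn_period = turn_period)
}

#' Calibration-movement scripts
#'
#' Deterministic scripts for the four functional-calibration movements, each
#' preceded by a short static stance:
#' * `squat_script()`: three slow squats (knee, hip and trunk flexion about
#'   the medio-lateral axes, pelvis dropping ~0.38 m);
#' * `trunk_rotation_script()`: three axial trunk rotations (+/-45 deg about
#'   the vertical axis, hips compensating so the legs stay put);
#' * `hip_abduction_script(side)`: three slow ab/adductions of one leg
#'   (+/-25 deg about the anterior-posterior axis, knee kept straight);
#' * `upright_script()`: 10 s upright stance with knees slightly flexed.
#'
#' @param rate sampling rate, Hz.
#' @param reps movement repetitions.
#' @param rep_period seconds per repetition.
#' @param lead static lead-in, seconds.
#' @return a `motion_script`.
#' @export
squat_script <- function(rate = 500, reps = 3, rep_period = 4, lead = 1.5) {
  dur <- lead + reps * rep_period + 0.5
  t <- seq(0, dur, by = 1 / rate)
  n <- length(t)
  u <- pmax(0, t - lead)
  e <- smoothstep(u / 1.0)
  s <- e * (1 - cos(2 * pi * u / rep_period)) / 2
  joints <- list(
    trunk  = .angles3(-20 * s, 0, 0, n),
    hip_l  = .angles3(-5 - 70 * s, 0, 0, n),
    hip_r  = .angles3(-5 - 70 * s, 0, 0, n),
    knee_l = .angles3(5 + 75 * s, 0, 0, n),
    knee_r = .angles3(5 + 75 * s, 0, 0, n)
  )
  pos <- cbind(-0.12 * s, 1.00 - 0.38 * s, 0 * s)
  q_root <- .root_quat(0, -30 * s, 0, n)
  .motion_script(t, rate, pos, q_root, joints)
}

#' @rdname squat_script
#' @export
trunk_rotation_script <- function(rate = 500, reps = 3, rep_period = 4,
                                  lead = 1.5) {
  dur <- lead + reps * rep_period + 0.5
  t <- seq(0, dur, by = 1 / rate)
  n <- length(t)
  u <- pmax(0, t - lead)
  e <- smoothstep(u / 1.0)
  yaw <- 45 * e * sin(2 * pi * u / rep_period)
  joints <- list(
    trunk  = .angles3(0, 0, 0, n),
    hip_l  = .angles3(-5, 0, -yaw, n),
    hip_r  = .angles3(-5, 0, -yaw, n),
    knee_l = .angles3(5, 0, 0, n),
    knee_r = .angles3(5, 0, 0, n)
  )
  pos <- cbind(0 * t, 1.00 + 0 * t, 0 * t)
  q_root <- .root_quat(yaw, 0, 0, n)
  .motion_script(t, rate, pos, q_root, joints)
}

#' @rdname squat_script
#' @param side `"left"` or `"right"`: the leg performing the ab/adduction.
#' @export
hip_abduction_script <- function(side = c("left", "right"), rate = 500,
                                 reps = 3, rep_period = 4, lead = 1.5) {
  side <- match.arg(side)
  dur <- lead + reps * rep_period + 0.5
  t <- seq(0, dur, by = 1 / rate)
  n <- length(t)
  u <- pmax(0, t - lead)
  e <- smoothstep(u / 1.0)
  # abduction away from the midline: +Z (right) leg swings to +X rotation,
  # left leg mirrored
  amp <- if (side == "right") 25 else -25
  abd <- amp * e * sin(2 * pi * u / rep_period)
  zero <- .angles3(0, 0, 0, n)
  joints <- list(
    trunk  = zero,
    hip_l  = if (side == "left") .angles3(0, abd, 0, n) else zero,
    hip_r  = if (side == "right") .angles3(0, abd, 0, n) else zero,
    knee_l = zero,
    knee_r = zero
  )
  pos <- cbind(0 * t, 1.00 + 0 * t, 0 * t)
  q_root <- .root_quat(0, 0, 0, n)
  .motion_script(t, rate, pos, q_root, joints)
}

#' @rdname squat_script
#' @param duration stance duration, seconds.
#' @export
upright_script <- function(rate = 500, duration = 10.5) {
  t <- seq(0, duration, by = 1 / rate)
  n <- length(t)
  joints <- list(
    trunk  = .angles3(0, 0, 0, n),
    hip_l  = .angles3(-5, 0, 0, n),
    hip_r  = .angles3(-5, 0, 0, n),
    knee_l = .angles3(5, 0, 0, n),
    knee_r = .angles3(5, 0, 0, n)
  )
  pos <- cbind(0 * t, 1.00 + 0 * t, 0 * t)
  q_root <- .root_quat(0, 0, 0, n)
  .motion_script(t, rate, pos, q_root, joints)
}

#' Simulate ground-truth kinematics of a chain following a motion script
#'
#' Propagates the scripted root pose and joint angles through the chain:
#' distal orientations are the proximal orientation composed with the
#' scripted joint rotation, joint-centre positions follow from the
#' sensor-to-joint vectors, and sensor positions are placed accordingly.
#' By construction, decomposing adjacent ground-truth orientations with
#' [grood_suntay()] recovers the scripted angles exactly.
#'
#' @param chain a `chain_model` from [ski_chain()].
#' @param script a `motion_script`.
#' @return a `chain_sim`: list with `t`, `rate`, `q` (named list of N x 4
#'   ground-truth orientation matrices per segment), `sensor_pos` and
#'   `joint_pos` (named lists of N x 3 position matrices), and the `script`.
#' @export
simulate_trial <- function(chain, script) {
  missing <- setdiff(names(chain$joints), names(script$joints))
  if (length(missing) > 0L) {
    stop(sprintf("script lacks trajectories for joint(s): %s",
                 paste(missing, collapse = ", ")))
  }
  n <- length(script$t)
  q <- list(); pos <- list(); jpos <- list()
  root <- names(chain$segments)[1L]
  q[[root]] <- as_quat_matrix(script$root$q)
  pos[[root]] <- as_vec3_matrix(script$root$pos)
  for (jn in names(chain$joints)) {
    j <- chain$joints[[jn]]
    ang <- script$joints[[jn]]
    if (is.null(q[[j$prox]])) stop("chain joints are not in topological order")
    q_rel <- jcs_compose(ang[, 1L], ang[, 2L], ang[, 3L])
    q[[j$dist]] <- quat_normalize(.quat_mult_raw(q[[j$prox]],
                                                 as_quat_matrix(q_rel)))
    jpos[[jn]] <- pos[[j$prox]] + quat_rotate(q[[j$prox]],
                                              matrix(j$r_p, n, 3L, byrow = TRUE))
    pos[[j$dist]] <- jpos[[jn]] - quat_rotate(q[[j$dist]],
                                              matrix(j$r_d, n, 3L, byrow = TRUE))
  }
  structure(list(t = script$t, rate = script$rate, q = q, sensor_pos = pos,
                 joint_pos = jpos, script = script),
            class = "chain_sim")
}

# Body-frame angular velocity from an orientation trace by central-difference
# quaternion logarithm.
body_rates_from_orientations <- function(q, rate) {
  q <- as_quat_matrix(q)
  n <- nrow(q)
  omega <- matrix(0, n, 3L)
  if (n >= 3L) {
    rel <- .quat_mult_raw(as_quat_matrix(quat_conjugate(q[1:(n - 2L), , drop = FALSE])),
                          q[3:n, , drop = FALSE])
    omega[2:(n - 1L), ] <- as_vec3_matrix(quat_log_vec(quat_normalize(rel))) * (rate / 2)
  }
  rel1 <- quat_normalize(.quat_mult_raw(as_quat_matrix(quat_conjugate(q[1L, ])),
                                        q[2L, , drop = FALSE]))
  omega[1L, ] <- quat_log_vec(rel1) * rate
  reln <- quat_normalize(.quat_mult_raw(as_quat_matrix(quat_conjugate(q[n - 1L, ])),
                                        q[n, , drop = FALSE]))
  omega[n, ] <- quat_log_vec(reln) * rate
  omega
}

# Second time derivative by central differences (ends copied inward).
second_derivative <- function(x, rate) {
  n <- nrow(x)
  d <- matrix(0, n, ncol(x))
  if (n >= 3L) {
    d[2:(n - 1L), ] <- (x[3:n, , drop = FALSE] - 2 * x[2:(n - 1L), , drop = FALSE] +
                          x[1:(n - 2L), , drop = FALSE]) * rate^2
    d[1L, ] <- d[2L, ]
    d[n, ] <- d[n - 1L, ]
  }
  d
}

#' Synthesize IMU signals from a ground-truth trace
#'
#' Gyroscope: body-frame angular velocity obtained by central-difference
#' quaternion logarithm of the (mounting-rotated) orientation trace.
#' Accelerometer: central second difference of the sensor position plus
#' gravity (9.81 m/s^2 along global +Y), rotated into the sensor frame.
#' Bias and white noise are added per the noise model; the RNG state of the
#' caller is preserved.
#'
#' @param t timestamps, seconds (uniform, >= 100 Hz).
#' @param q N x 4 ground-truth segment orientation matrix.
#' @param pos N x 3 sensor position matrix, metres.
#' @param noise a [noise_model] or NULL for noise-free output; the bias of
#'   this model (after `bias_sign`) is added to the gyroscope.
#' @param mounting mounting quaternion (sensor to anatomical frame).
#' @param bias_sign +1 or -1 multiplier on the gyro bias vector.
#' @param segment segment label for the output stream.
#' @return an [imu_stream] in the sensor frame.
#' @export
synthesize_imu <- function(t, q, pos, noise = NULL,
                           mounting = quat_identity(), bias_sign = 1,
                           segment = "unknown") {
  q <- as_quat_matrix(q); pos <- as_vec3_matrix(pos)
  dt <- diff(t)
  rate <- 1 / stats::median(dt)
  if (max(abs(dt - 1 / rate)) > 1e-6) stop("non-uniform sampling in ground-truth trace")
  if (rate < 100 * (1 - 1e-9)) stop("ground-truth trace must be sampled at >= 100 Hz")
  q_sensor <- quat_normalize(.quat_mult_raw(q, as_quat_matrix(mounting)))
  gyro <- body_rates_from_orientations(q_sensor, rate)
  acc_g <- second_derivative(pos, rate)
  acc_g[, 2L] <- acc_g[, 2L] + GRAVITY
  accel <- quat_rotate(quat_conjugate(q_sensor), acc_g)
  if (!is.null(noise)) {
    gyro <- sweep(gyro, 2L, bias_sign * noise$gyro_bias, `+`)
    if (noise$gyro_noise_sd > 0 || noise$accel_noise_sd > 0) {
      n <- nrow(gyro)
      noise_draw <- with_seed(noise$seed, {
        list(g = matrix(stats::rnorm(3L * n, sd = noise$gyro_noise_sd), n, 3L),
             a = matrix(stats::rnorm(3L * n, sd = noise$accel_noise_sd), n, 3L))
      })
      gyro <- gyro + noise_draw$g
      accel <- accel + noise_draw$a
    }
  }
  imu_stream(t, accel, gyro, rate = rate, segment = segment)
}

# Deterministic per-(segment, movement) sub-seed.
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 13 + as.numeric(k) * 7919) %% 2147483647)
}

#' Synthesize IMU streams for every segment of a simulated trial
#'
#' @param sim a `chain_sim` from [simulate_trial()].
#' @param chain the `chain_model` (provides mountings and bias signs).
#' @param noise a [noise_model] or NULL; each segment receives an
#'   independent white-noise stream derived deterministically from the
#'   model's seed, and the bias sign stored in the chain.
#' @param segments segment names to synthesize (default: all).
#' @return named list of [imu_stream]s.
#' @export
synthesize_trial_imu <- function(sim, chain, noise = NULL,
                                 segments = names(chain$segments)) {
  out <- list()
  for (i in seq_along(segments)) {
    nm <- segments[[i]]
    seg <- chain$segments[[nm]]
    nz <- noise
    if (!is.null(nz) && !is.null(nz$seed)) {
      nz$seed <- .sub_seed(nz$seed, match(nm, names(chain$segments)))
    }
    out[[nm]] <- synthesize_imu(sim$t, sim$q[[nm]], sim$sensor_pos[[nm]],
                                noise = nz, mounting = seg$mounting,
                                bias_sign = seg$bias_sign, segment = nm)
  }
  out
}

#' Simulate the four functional-calibration movements
#'
#' Runs the calibration scripts through the chain and synthesizes IMU
#' streams for every segment. In the noise-free, identity-mounting case the
#' streams satisfy the calibration hypotheses exactly: the squat rotation
#' axis is each segment's medio-lateral axis, trunk rotations occur about
#' the vertical axis, ab/adductions about the anterior-posterior axis, and
#' the upright stance is static with knees slightly flexed.
#'
#' @param chain a `chain_model`; its mounting quaternions are the simulated
#'   misalignments the calibration should recover.
#' @param noise a [noise_model] or NULL; per movement a distinct sub-seed is
#'   drawn from the model's seed.
#' @param rate sampling rate, Hz.
#' @return list with `movements` (named list: squats, trunk_rotations,
#'   hip_abduction_left, hip_abduction_right, upright; each a named list of
#'   [imu_stream]s per segment) and `truth` (the corresponding `chain_sim`s).
#' @export
simulate_calibration_movements <- function(chain, noise = NULL, rate = 500) {
  scripts <- list(
    squats = squat_script(rate = rate),
    trunk_rotations = trunk_rotation_script(rate = rate),
    hip_abduction_left = hip_abduction_script("left", rate = rate),
    hip_abduction_right = hip_abduction_script("right", rate = rate),
    upright = upright_script(rate = rate)
  )
  movements <- list(); truth <- list()
  for (i in seq_along(scripts)) {
    mv <- names(scripts)[[i]]
    sim <- simulate_trial(chain, scripts[[i]])
    nz <- noise
    if (!is.null(nz) && !is.null(nz$seed)) nz$seed <- .sub_seed(nz$seed, 100L + i)
    movements[[mv]] <- synthesize_trial_imu(sim, chain, noise = nz)
    truth[[mv]] <- sim
  }
  list(movements = movements, truth = truth)
}

#' Random mounting misalignment
#'
#' Draws a rotation with uniformly random axis and angle uniform in
#' `[0, max_angle_deg]`, for misalignment-recovery studies.
#'
#' @param max_angle_deg maximum misalignment angle, degrees.
#' @return a unit quaternion.
#' @export
random_mounting <- function(max_angle_deg = 30) {
  axis <- stats::rnorm(3L)
  axis <- axis / sqrt(sum(axis^2))
  quat_from_axis_angle(axis, deg2rad(stats::runif(1L, 0, max_angle_deg)))
}
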