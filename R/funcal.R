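#' Functional sensor-to-segment calibration
#'
#' Ski boots make a neutral reference posture impossible (they impose about
#' 17 degrees of ankle flexion), so sensor-to-segment alignment is estimated
#' from four movements executable on skis: squats, trunk rotations, hip
#' ab/adductions and upright standing. Each segment's anatomical axes are
#' reconstructed in its sensor frame from the dominant rotation axes of
#' these movements plus gravity, and the lower-limb frames are then refined
#' with biomechanical constraints (zero mean knee flexion during
#' ab/adduction, medio-lateral axes perpendicular to gravity when upright,
#' left/right symmetry at squat start).
#'
#' The calibration quaternion `q_cal` of a segment rotates sensor-frame
#' coordinates into the segment's anatomical frame (X anterior, Y superior,
#' Z right).
#'
#' @name funcal
NULL

#' Cut a time window out of a stream
#' @param stream an [imu_stream].
#' @param from,to window boundaries in seconds (inclusive).
#' @return the windowed [imu_stream].
#' @export
stream_window <- function(stream, from, to) {
  keep <- stream$t >= from - 1e-9 & stream$t <= to + 1e-9
  if (sum(keep) < 2L) stop("window contains fewer than 2 samples")
  imu_stream(stream$t[keep], stream$accel[keep, , drop = FALSE],
             stream$gyro[keep, , drop = FALSE], rate = stream$rate,
             segment = stream$segment)
}

#' Dominant rotation axis of a movement window
#'
#' First principal direction of the angular-velocity samples, weighted by
#' rate magnitude so near-static samples do not dilute the estimate. The
#' sign is chosen so the mean projection of the angular velocity onto the
#' axis is positive, unless a reference direction is supplied (as the
#' calibration routines do, since for symmetric back-and-forth movements
#' the mean projection is near zero).
#'
#' @param gyro an [imu_stream] or N x 3 gyro matrix, rad/s.
#' @param min_peak_deg_s minimum peak rate for the window to count as a
#'   movement, deg/s.
#' @param ref_axis optional reference direction fixing the sign.
#' @return unit 3-vector in the sensor frame.
#' @export
estimate_rotation_axis <- function(gyro, min_peak_deg_s = 20, ref_axis = NULL) {
  g <- if (inherits(gyro, "imu_stream")) gyro$gyro else as_vec3_matrix(gyro)
  mag <- vec3_norm(g)
  if (max(mag) < deg2rad(min_peak_deg_s)) {
    stop(sprintf("insufficient rotation: peak %.1f deg/s < %.1f deg/s",
                 rad2deg(max(mag)), min_peak_deg_s))
  }
  M <- crossprod(g * sqrt(mag))
  axis <- eigen(M, symmetric = TRUE)$vectors[, 1L]
  axis <- axis / sqrt(sum(axis^2))
  if (!is.null(ref_axis)) {
    if (sum(axis * ref_axis) < 0) axis <- -axis
  } else if (sum(g %*% axis) < 0) {
    axis <- -axis
  }
  axis
}

#' Gravity (superior) axis from a quasi-static window
#'
#' Normalised mean acceleration; when the segment is upright this points
#' along the gravity reaction, i.e. the anatomical superior direction.
#'
#' @param accel an [imu_stream] or N x 3 accelerometer matrix, m/s^2.
#' @param tol_mag admissible range of the mean magnitude; outside it the
#'   window is rejected as movement-contaminated.
#' @return unit 3-vector in the sensor frame.
#' @export
estimate_gravity_axis <- function(accel, tol_mag = c(9.0, 10.6)) {
  a <- if (inherits(accel, "imu_stream")) accel$accel else as_vec3_matrix(accel)
  m <- colMeans(a)
  mn <- sqrt(sum(m^2))
  if (mn < tol_mag[1L] || mn > tol_mag[2L]) {
    stop(sprintf("movement contamination: |mean accel| = %.2f m/s^2 outside [%g, %g]",
                 mn, tol_mag[1L], tol_mag[2L]))
  }
  m / mn
}

# Right-handed orthonormal frame from a superior axis (kept exact) and a
# medio-lateral axis (projected orthogonal); columns x (anterior),
# y (superior), z (right) in sensor coordinates.
.frame_from_sup_ml <- function(sup, ml, collinear_deg = 20) {
  ang <- rad2deg(acos(pmin(1, abs(sum(sup * ml)))))
  if (ang < collinear_deg) {
    stop(sprintf("calibration axes nearly collinear (%.1f deg apart)", ang))
  }
  z <- ml - sum(ml * sup) * sup
  z <- z / sqrt(sum(z^2))
  x <- cross3(sup, z)
  cbind(x, sup, z, deparse.level = 0L)
}

.quat_from_axes <- function(C) quat_from_matrix(t(C))

.new_calibration <- function(q, diagnostics) {
  structure(list(q = quat_canonical(q), diagnostics = diagnostics),
            class = "segment_calibration")
}

#' @export
print.segment_calibration <- function(x, ...) {
  aa <- axis_angle_of(x$q)
  cat(sprintf("<segment_calibration> rotation %.2f deg about (%.2f, %.2f, %.2f)\n",
              rad2deg(aa$angle), aa$axis[1L], aa$axis[2L], aa$axis[3L]))
  invisible(x)
}

#' Calibrate a trunk or head sensor
#'
#' Hypotheses: squats rotate the segment about its medio-lateral axis,
#' trunk rotations about the vertical axis, and the trunk is perfectly
#' vertical during upright standing. The anatomical frame keeps the
#' upright gravity direction as the exact superior axis, projects the squat
#' axis orthogonal to it for medio-lateral, and completes right-handed;
#' the trunk-rotation axis serves as a consistency check whose residual
#' angle to the superior axis is reported.
#'
#' @param squat,trunk_rotation,upright [imu_stream] windows of the three
#'   movements for this sensor.
#' @return a `segment_calibration` (fields `q`, `diagnostics`).
#' @export
calibrate_trunk <- function(squat, trunk_rotation, upright) {
  ml <- estimate_rotation_axis(squat, ref_axis = c(0, 0, 1))
  sup <- estimate_gravity_axis(upright)
  C <- .frame_from_sup_ml(sup, ml)
  vert <- estimate_rotation_axis(trunk_rotation, ref_axis = c(0, 1, 0))
  resid <- rad2deg(acos(pmin(1, abs(sum(vert * sup)))))
  .new_calibration(.quat_from_axes(C),
                   list(vertical_axis_residual_deg = resid))
}

#' Calibrate a shank sensor
#'
#' Hypotheses: hip ab/adduction rotates the (straight) leg about the
#' anterior-posterior axis, and at the beginning of the movement the
#' medio-lateral axis is perpendicular to gravity. The ab/adduction axis is
#' kept exact as anterior-posterior; medio-lateral is the cross product of
#' that axis with the gravity direction measured over the static lead-in.
#'
#' @param abduction [imu_stream] window of the correct-side ab/adduction.
#' @param static_s duration of the quasi-static lead-in at the start of the
#'   window used for gravity, seconds.
#' @return a `segment_calibration`.
#' @export
calibrate_shank <- function(abduction, static_s = 1) {
  ap <- estimate_rotation_axis(abduction, ref_axis = c(1, 0, 0))
  lead <- stream_window(abduction, abduction$t[1L], abduction$t[1L] + static_s)
  g <- estimate_gravity_axis(lead)
  ang <- rad2deg(acos(pmin(1, abs(sum(ap * g)))))
  if (ang < 20) stop("ab/adduction axis nearly collinear with gravity")
  z <- cross3(ap, g)
  z <- z / sqrt(sum(z^2))
  y <- cross3(z, ap)
  C <- cbind(ap, y, z, deparse.level = 0L)
  .new_calibration(.quat_from_axes(C),
                   list(gravity_axis_angle_deg = 90 - ang))
}

# Sensor-frame global orientation trace over a movement window:
# strap-down increments anchored so that the candidate anatomical frame has
# zero azimuth and gravity-derived inclination over the static lead-in.
.anchored_sensor_trace <- function(stream, q_cal, static_s = 1) {
  inc <- integrate_increments(stream$gyro, 1 / stream$rate)
  lead <- stream$t <= stream$t[1L] + static_s
  a0 <- colMeans(stream$accel[lead, , drop = FALSE])
  a0_anat <- quat_rotate(q_cal, a0)
  q_a0 <- initial_orientation(a0_anat)
  q_s0 <- quat_multiply(q_a0, q_cal)
  quat_normalize(.quat_mult_raw(as_quat_matrix(q_s0), inc))
}

#' Calibrate a thigh sensor
#'
#' The squat fixes the thigh's medio-lateral axis; the rotation about that
#' axis is resolved by requiring that lower-back and thigh accelerations,
#' translated to the hip joint centre by rigid-body kinematics and expressed
#' in the global frame, agree in direction over the squat. A 1-D search
#' over the residual rotation angle minimises the mean orientation
#' difference between the two translated acceleration vectors; fixing the
#' sensor-to-hip-centre vectors to (0.05, -0.10, 0) m (lower back) and
#' (-0.05, 0.30, 0) m (thigh) is sufficient.
#'
#' @param squat_thigh,upright_thigh [imu_stream] windows for the thigh.
#' @param squat_lowerback lower-back [imu_stream] over the same squat
#'   window (time-synchronised).
#' @param cal_lowerback the lower back's `segment_calibration`.
#' @param r_lb,r_th sensor-to-hip-centre vectors, anatomical frames, m.
#' @param static_s static lead-in used to anchor orientations, seconds.
#' @param search_deg half-width of the 1-D search interval, degrees.
#' @param decimate evaluate the objective on every `decimate`-th sample.
#' @return a `segment_calibration`; `diagnostics$objective` is the
#'   objective function (argument in degrees, value = mean orientation
#'   difference in degrees) for auditing the optimisation.
#' @export
calibrate_thigh <- function(squat_thigh, upright_thigh, squat_lowerback,
                            cal_lowerback,
                            r_lb = c(0.05, -0.10, 0), r_th = c(-0.05, 0.30, 0),
                            static_s = 1, search_deg = 30, decimate = 5L) {
  ml <- estimate_rotation_axis(squat_thigh, ref_axis = c(0, 0, 1))
  sup0 <- estimate_gravity_axis(upright_thigh)
  C0 <- .frame_from_sup_ml(sup0, ml)
  # re-extract the basis: keep the squat axis exact for the search
  z <- C0[, 3L]; y0 <- cross3(z, C0[, 1L]); x0 <- C0[, 1L]

  # fixed lower-back side
  q_lb <- cal_lowerback$q
  qs_lb <- .anchored_sensor_trace(squat_lowerback, q_lb, static_s)
  od_lb <- gyro_derivative(squat_lowerback$gyro, squat_lowerback$rate)
  r_lb_s <- quat_rotate(quat_conjugate(q_lb), r_lb)
  a_lb <- translate_acceleration(squat_lowerback$accel, squat_lowerback$gyro,
                                 od_lb, r_lb_s)
  a_lb_g <- quat_rotate(qs_lb, a_lb)

  # thigh side: increments are theta-independent, only the anchor varies
  inc_th <- integrate_increments(squat_thigh$gyro, 1 / squat_thigh$rate)
  od_th <- gyro_derivative(squat_thigh$gyro, squat_thigh$rate)
  lead <- squat_thigh$t <= squat_thigh$t[1L] + static_s
  a0 <- colMeans(squat_thigh$accel[lead, , drop = FALSE])
  idx <- seq(1L, nrow(inc_th), by = decimate)
  a_lb_g_d <- a_lb_g[idx, , drop = FALSE]

  objective <- function(theta_deg) {
    th <- deg2rad(theta_deg)
    xt <- cos(th) * x0 + sin(th) * y0
    yt <- cos(th) * y0 - sin(th) * x0
    C <- cbind(xt, yt, z, deparse.level = 0L)
    q_cal <- .quat_from_axes(C)
    r_s <- drop(C %*% r_th)
    a_tr <- translate_acceleration(squat_thigh$accel[idx, , drop = FALSE],
                                   squat_thigh$gyro[idx, , drop = FALSE],
                                   od_th[idx, , drop = FALSE], r_s)
    q_a0 <- initial_orientation(quat_rotate(q_cal, a0))
    q_s0 <- quat_multiply(q_a0, q_cal)
    qs <- quat_normalize(.quat_mult_raw(as_quat_matrix(q_s0),
                                        inc_th[idx, , drop = FALSE]))
    a_th_g <- quat_rotate(qs, a_tr)
    dot <- rowSums(a_th_g * a_lb_g_d) /
      pmax(vec3_norm(a_th_g) * vec3_norm(a_lb_g_d), 1e-300)
    mean(rad2deg(acos(pmin(1, pmax(-1, dot)))))
  }
  opt <- stats::optimize(objective, interval = c(-search_deg, search_deg),
                         tol = 1e-3)
  # guard against a poor golden-section bracket on a flat objective
  grid <- seq(-search_deg, search_deg, by = 2)
  gv <- vapply(grid, objective, numeric(1L))
  if (min(gv) < opt$objective - 1e-6) {
    opt <- stats::optimize(objective,
                           interval = grid[which.min(gv)] + c(-3, 3), tol = 1e-3)
  }
  th <- deg2rad(opt$minimum)
  C <- cbind(cos(th) * x0 + sin(th) * y0, cos(th) * y0 - sin(th) * x0, z,
             deparse.level = 0L)
  .new_calibration(.quat_from_axes(C),
                   list(theta_deg = opt$minimum,
                        objective_min_deg = opt$objective,
                        objective = objective))
}

# Anatomical gravity direction of a segment over the first static_s seconds
# of a stream, under a given calibration.
.static_gravity_anat <- function(stream, q_cal, static_s = 1) {
  lead <- stream_window(stream, stream$t[1L], stream$t[1L] + static_s)
  quat_rotate(q_cal, estimate_gravity_axis(lead))
}

#' Refine lower-limb calibrations with biomechanical constraints
#'
#' Applies three constraints as small corrective rotations, iterated twice:
#' 1. the medio-lateral axis of every shank and thigh is perpendicular to
#'    gravity during upright standing (minimal rotation moving the measured
#'    gravity direction into the segment's sagittal plane);
#' 2. average knee flexion during the hip ab/adduction is zero (rotation of
#'    the thigh calibration about its medio-lateral axis — the shank's
#'    sagittal alignment is already pinned by gravity and is left alone);
#' 3. left and right shanks/thighs have the same inclination at the
#'    beginning of the squat (the mismatch rotation is split half/half).
#'
#' @param cals named list of `segment_calibration`s with entries
#'   `thigh_l`, `thigh_r`, `shank_l`, `shank_r` (others pass through).
#' @param movements named list of per-movement stream lists as returned in
#'   `simulate_calibration_movements()$movements` (or equivalently windowed
#'   field data): `upright`, `hip_abduction_left`, `hip_abduction_right`,
#'   `squats`.
#' @param static_s static lead-in seconds for gravity anchors.
#' @param n_iter constraint sweeps (default 2).
#' @param max_correction_deg total correction beyond which the movement is
#'   flagged as mis-executed (error), degrees.
#' @return list with `cals` (refined calibrations) and `report`
#'   (data.frame of residuals per constraint before and after).
#' @export
refine_lower_limb <- function(cals, movements, static_s = 1, n_iter = 2L,
                              max_correction_deg = 25) {
  limb <- c("shank_l", "shank_r", "thigh_l", "thigh_r")
  stopifnot(all(limb %in% names(cals)))
  total <- stats::setNames(rep(0, length(limb)), limb)

  gravity_resid <- function(cs) {
    vapply(limb, function(nm) {
      g <- .static_gravity_anat(movements$upright[[nm]], cs[[nm]]$q, static_s)
      abs(90 - rad2deg(acos(pmin(1, pmax(-1, abs(g[3L]))))))
    }, numeric(1L))
  }
  knee_flex_mean <- function(cs, side) {
    mv <- movements[[paste0("hip_abduction_", side)]]
    th <- mv[[paste0("thigh_", substr(side, 1L, 1L))]]
    sh <- mv[[paste0("shank_", substr(side, 1L, 1L))]]
    q_th <- .anchored_sensor_trace(th, cs[[paste0("thigh_", substr(side, 1L, 1L))]]$q, static_s)
    q_sh <- .anchored_sensor_trace(sh, cs[[paste0("shank_", substr(side, 1L, 1L))]]$q, static_s)
    qa_th <- quat_normalize(.quat_mult_raw(q_th, as_quat_matrix(
      quat_conjugate(cs[[paste0("thigh_", substr(side, 1L, 1L))]]$q))))
    qa_sh <- quat_normalize(.quat_mult_raw(q_sh, as_quat_matrix(
      quat_conjugate(cs[[paste0("shank_", substr(side, 1L, 1L))]]$q))))
    ang <- jcs_decompose(.relative_quats(qa_th, qa_sh))
    mean(ang$flexion)
  }
  symmetry_resid <- function(cs, what) {
    gl <- .static_gravity_anat(movements$squats[[paste0(what, "_l")]],
                               cs[[paste0(what, "_l")]]$q, static_s)
    gr <- .static_gravity_anat(movements$squats[[paste0(what, "_r")]],
                               cs[[paste0(what, "_r")]]$q, static_s)
    rad2deg(acos(pmin(1, sum(gl * gr))))
  }

  before <- c(gravity = max(gravity_resid(cals)),
              knee_flexion_left = knee_flex_mean(cals, "left"),
              knee_flexion_right = knee_flex_mean(cals, "right"),
              symmetry_shank = symmetry_resid(cals, "shank"),
              symmetry_thigh = symmetry_resid(cals, "thigh"))

  apply_corr <- function(nm, r) {
    cals[[nm]]$q <<- quat_canonical(quat_multiply(r, cals[[nm]]$q))
    total[[nm]] <<- total[[nm]] + rad2deg(quat_angle(r))
  }

  for (iter in seq_len(n_iter)) {
    # 1. medio-lateral axes perpendicular to gravity when upright
    for (nm in limb) {
      g <- .static_gravity_anat(movements$upright[[nm]], cals[[nm]]$q, static_s)
      proj <- g; proj[3L] <- 0
      if (sqrt(sum(proj^2)) > 1e-9) {
        apply_corr(nm, quat_between_vectors(g, proj))
      }
    }
    # 2. zero mean knee flexion during ab/adduction (thigh pitch)
    for (side in c("left", "right")) {
      phi <- knee_flex_mean(cals, side)
      apply_corr(paste0("thigh_", substr(side, 1L, 1L)),
                 quat_from_axis_angle(c(0, 0, 1), deg2rad(-phi)))
    }
    # 3. left/right symmetry at squat start (split half/half)
    for (what in c("shank", "thigh")) {
      gl <- .static_gravity_anat(movements$squats[[paste0(what, "_l")]],
                                 cals[[paste0(what, "_l")]]$q, static_s)
      gr <- .static_gravity_anat(movements$squats[[paste0(what, "_r")]],
                                 cals[[paste0(what, "_r")]]$q, static_s)
      m <- quat_between_vectors(gl, gr)
      half <- quat_slerp(quat_identity(), m, 0.5)
      apply_corr(paste0(what, "_l"), half)
      apply_corr(paste0(what, "_r"), quat_conjugate(half))
    }
  }
  if (any(total > max_correction_deg)) {
    stop(sprintf("refinement corrections exceed %g deg (%s): calibration movements likely mis-executed",
                 max_correction_deg,
                 paste(sprintf("%s %.1f", names(total), total), collapse = ", ")))
  }
  after <- c(gravity = max(gravity_resid(cals)),
             knee_flexion_left = knee_flex_mean(cals, "left"),
             knee_flexion_right = knee_flex_mean(cals, "right"),
             symmetry_shank = symmetry_resid(cals, "shank"),
             symmetry_thigh = symmetry_resid(cals, "thigh"))
  list(cals = cals,
       report = data.frame(constraint = names(before),
                           before_deg = as.numeric(before),
                           after_deg = as.numeric(after)),
       correction_deg = total)
}

#' Run the full functional calibration for all segments
#'
#' Convenience driver: trunk-style calibration for the lower back and
#' sternum, thigh calibration (using the lower-back result), shank
#' calibration per side, then the lower-limb refinement.
#'
#' @param calmov output of [simulate_calibration_movements()] (`$movements`
#'   element) or an equivalently structured list of windowed field streams.
#' @param r_lb,r_th sensor-to-hip-centre vectors passed to
#'   [calibrate_thigh()].
#' @param refine run [refine_lower_limb()] (default TRUE).
#' @return a `calibration_result`: named list of `segment_calibration`s
#'   plus attribute `refinement` (the refinement report, when run).
#' @export
calibrate_all <- function(calmov, r_lb = c(0.05, -0.10, 0),
                          r_th = c(-0.05, 0.30, 0), refine = TRUE) {
  mv <- if (!is.null(calmov$movements)) calmov$movements else calmov
  cals <- list()
  for (nm in c("lower_back", "sternum")) {
    cals[[nm]] <- calibrate_trunk(mv$squats[[nm]], mv$trunk_rotations[[nm]],
                                  mv$upright[[nm]])
  }
  for (side in c("l", "r")) {
    cals[[paste0("thigh_", side)]] <- calibrate_thigh(
      mv$squats[[paste0("thigh_", side)]], mv$upright[[paste0("thigh_", side)]],
      mv$squats$lower_back, cals$lower_back, r_lb = r_lb, r_th = r_th)
    abd <- mv[[paste0("hip_abduction_", if (side == "l") "left" else "right")]]
    cals[[paste0("shank_", side)]] <- calibrate_shank(abd[[paste0("shank_", side)]])
  }
  refinement <- NULL
  if (refine) {
    ref <- refine_lower_limb(cals, mv)
    cals <- ref$cals
    refinement <- ref$report
  }
  attr(cals, "refinement") <- refinement
  class(cals) <- c("calibration_result", class(cals))
  cals
}

#' Dispersion of repeated calibration quaternions
#'
#' Spread of F repeated calibrations `q_F` around their rotation mean
#' `q_bar`: each deviation is the geodesic angle
#' `Delta_F = 2 acos(|Re(q_bar (x) q_F^-1)|)` (degrees) and the dispersion
#' is `chi = sqrt(sum(Delta^2) / (N - 1))`. Note: a literal reading of the
#' defining equation would take `2 cos(.)`, which cannot yield an angle;
#' the standard geodesic form with `acos` is used.
#'
#' @param quats list of unit quaternions, or an N x 4 matrix (N >= 2).
#' @return dispersion in degrees.
#' @export
dispersion_chi <- function(quats) {
  qm <- if (is.list(quats)) do.call(rbind, quats) else as_quat_matrix(quats)
  if (nrow(qm) < 2L) stop("dispersion needs at least 2 quaternions")
  qbar <- quat_mean(qm)
  rel <- .quat_mult_raw(as_quat_matrix(qbar), as_quat_matrix(quat_conjugate(qm)))
  rel <- rel / sqrt(rowSums(rel^2))
  delta <- rad2deg(2 * acos(pmin(1, abs(rel[, 1L]))))
  sqrt(sum(delta^2) / (nrow(qm) - 1L))
}
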