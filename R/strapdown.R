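#' Strap-down orientation tracking and joint-drift correction
#'
#' Segment orientations are obtained by integrating calibrated angular
#' velocity (strap-down integration). Gyroscope bias and noise make the
#' integrated orientation drift; the correction implemented here exploits the
#' joint acceleration constraint: accelerations measured on two segments
#' sharing a joint, translated to that joint by rigid-body kinematics, must
#' coincide once expressed in the global frame. Any orientation mismatch
#' between the two translated acceleration vectors is attributed to drift of
#' the distal segment and removed.
#'
#' Because gravity dominates the measured acceleration, the mismatch mostly
#' constrains rotations about horizontal axes: heading (azimuth) drift is
#' nearly unobservable in a first pass. A second pass therefore zeroes the
#' vertical (global Y) component of the translated accelerations and
#' re-estimates drift from the horizontal components only, constraining the
#' resulting correction to a rotation about the vertical axis.
#'
#' @name strapdown
NULL

GRAVITY <- 9.81

#' Initial segment orientation from a static acceleration window
#'
#' Inclination (roll/pitch with respect to gravity) is taken from the mean
#' measured acceleration; heading cannot be observed without a magnetometer,
#' so all segments are initialised to a common azimuth (default zero: the
#' anatomical anterior axis faces the fall line). This is exact when the
#' athlete stands facing the fall line at trial start.
#'
#' @param accel N x 3 matrix of accelerometer samples (anatomical frame,
#'   m/s^2) over a quasi-static window, or a single mean 3-vector.
#' @param azimuth heading angle to assign, radians about global Y (default 0).
#' @param tol_mag acceptable range of the mean acceleration magnitude
#'   (m/s^2); outside it the window is rejected as non-static.
#' @param tol_sd maximum standard deviation of the acceleration magnitude
#'   within the window (m/s^2), ignored when a single vector is given.
#' @return unit quaternion: anatomical frame to global frame at t = 0.
#' @export
initial_orientation <- function(accel, azimuth = 0, tol_mag = c(9.0, 10.6),
                                tol_sd = 0.5) {
  am <- as_vec3_matrix(accel)
  mags <- vec3_norm(am)
  m <- colMeans(am)
  mn <- sqrt(sum(m^2))
  if (mn < tol_mag[1L] || mn > tol_mag[2L]) {
    stop(sprintf("non-static initial window: |mean accel| = %.2f m/s^2", mn))
  }
  if (nrow(am) > 1L && stats::sd(mags) > tol_sd) {
    stop(sprintf("non-static initial window: accel magnitude SD = %.2f m/s^2",
                 stats::sd(mags)))
  }
  # inclination: rotate measured gravity reaction onto global +Y
  q0 <- quat_between_vectors(m, c(0, 1, 0))
  # remove residual heading of the body X (anterior) axis, then set azimuth
  xg <- quat_rotate(q0, c(1, 0, 0))
  heading <- atan2(-xg[3L], xg[1L])
  quat_multiply(quat_from_axis_angle(c(0, 1, 0), azimuth - heading), q0)
}

# Accumulated orientation increments from identity: Q[i] such that
# q(t_i) = q0 (x) Q[i]. Trapezoidal angular-rate average per step.
integrate_increments <- function(gyro, dt) {
  n <- nrow(gyro)
  out <- matrix(0, n, 4L)
  out[1L, ] <- c(1, 0, 0, 0)
  w <- 1; x <- 0; y <- 0; z <- 0
  g1 <- gyro[, 1L]; g2 <- gyro[, 2L]; g3 <- gyro[, 3L]
  for (i in seq_len(n - 1L)) {
    rx <- (g1[i] + g1[i + 1L]) * 0.5 * dt
    ry <- (g2[i] + g2[i + 1L]) * 0.5 * dt
    rz <- (g3[i] + g3[i + 1L]) * 0.5 * dt
    th <- sqrt(rx * rx + ry * ry + rz * rz)
    if (th > 1e-12) {
      h <- th * 0.5
      cw <- cos(h); k <- sin(h) / th
      dx <- rx * k; dy <- ry * k; dz <- rz * k
    } else {
      cw <- 1; dx <- rx * 0.5; dy <- ry * 0.5; dz <- rz * 0.5
    }
    nw <- w * cw - x * dx - y * dy - z * dz
    nx <- w * dx + x * cw + y * dz - z * dy
    ny <- w * dy - x * dz + y * cw + z * dx
    nz <- w * dz + x * dy - y * dx + z * cw
    nn <- 1 / sqrt(nw * nw + nx * nx + ny * ny + nz * nz)
    w <- nw * nn; x <- nx * nn; y <- ny * nn; z <- nz * nn
    out[i + 1L, ] <- c(w, x, y, z)
  }
  out
}

#' Strap-down integration of angular velocity
#'
#' Integrates body-frame angular velocity into an orientation trace using
#' exact axis-angle (exponential map) increments per sample; the rate over
#' each step is the trapezoidal average of the two adjacent gyroscope
#' samples. Gyroscope offset must already be removed and, if joint angles are
#' wanted downstream, the sensor-to-segment calibration applied.
#'
#' @param stream an [imu_stream] (gyro in rad/s, body = anatomical frame).
#' @param q0 initial orientation (unit quaternion, body to global).
#' @return an [orientation_trace].
#' @export
strapdown_integrate <- function(stream, q0) {
  if (!all(is.finite(stream$gyro))) stop("NaN or Inf in gyroscope signal")
  .check_unit(q0, "initial orientation")
  inc <- integrate_increments(stream$gyro, 1 / stream$rate)
  q <- quat_normalize(.quat_mult_raw(as_quat_matrix(q0), inc))
  orientation_trace(stream$t, q, segment = stream$segment)
}

#' Translate measured acceleration to a joint point
#'
#' Rigid-body kinematics: `a_joint = a + domega/dt x r + omega x (omega x r)`
#' with all quantities in the same (sensor or anatomical) frame and `r` the
#' vector from the sensor to the joint in metres.
#'
#' @param a acceleration(s), 3-vector or N x 3 (m/s^2).
#' @param omega angular velocity(ies), same shape (rad/s).
#' @param omega_dot angular acceleration(s), same shape (rad/s^2).
#' @param r sensor-to-joint vector(s), 3-vector or N x 3 (m).
#' @return translated acceleration(s), same shape as `a`.
#' @export
translate_acceleration <- function(a, omega, omega_dot, r) {
  vec <- !is.matrix(a)
  am <- as_vec3_matrix(a)
  om <- as_vec3_matrix(omega); od <- as_vec3_matrix(omega_dot)
  rm <- as_vec3_matrix(r)
  if (!all(is.finite(am)) || !all(is.finite(om)) || !all(is.finite(od))) {
    stop("non-finite input to translate_acceleration")
  }
  out <- am + cross3(od, rm) + cross3(om, cross3(om, rm))
  .shape_like(as_vec3_matrix(out), vec)
}

#' Angular acceleration by filtered central differences
#'
#' The gyroscope signal is zero-phase low-passed (default 10 Hz) and
#' differentiated with central differences (one-sided at the edges).
#'
#' @param gyro N x 3 angular velocity, rad/s.
#' @param rate sampling rate, Hz.
#' @param cutoff_hz low-pass cutoff before differentiation.
#' @return N x 3 angular acceleration, rad/s^2.
#' @export
gyro_derivative <- function(gyro, rate, cutoff_hz = 10) {
  gf <- lowpass_cols(gyro, rate, cutoff_hz)
  n <- nrow(gf)
  d <- matrix(0, n, 3L)
  if (n >= 3L) {
    d[2:(n - 1L), ] <- (gf[3:n, , drop = FALSE] - gf[1:(n - 2L), , drop = FALSE]) * (rate / 2)
  }
  d[1L, ] <- (gf[2L, ] - gf[1L, ]) * rate
  d[n, ] <- (gf[n, ] - gf[n - 1L, ]) * rate
  d
}

#' Joint acceleration in the global frame
#'
#' Translates a calibrated stream's acceleration to the joint (anatomical
#' frame) and rotates it into the global frame with the segment's estimated
#' orientation trace.
#'
#' @param trace [orientation_trace] of the segment.
#' @param stream calibrated [imu_stream] of the same segment.
#' @param r sensor-to-joint vector in the anatomical frame, metres.
#' @param omega_dot optional precomputed angular acceleration (N x 3).
#' @return N x 3 matrix: translated acceleration at the joint, global frame.
#' @export
joint_acceleration_global <- function(trace, stream, r, omega_dot = NULL) {
  if (is.null(omega_dot)) omega_dot <- gyro_derivative(stream$gyro, stream$rate)
  aj <- translate_acceleration(stream$accel, stream$gyro, omega_dot, r)
  quat_rotate(trace$q, aj)
}

#' Valid-sample mask for drift estimation
#'
#' A sample contributes to the drift estimate only when both translated
#' acceleration magnitudes exceed `th_max` (6 m/s^2 by default) and their
#' magnitudes agree to within `rel_tol` (20%) of their mean:
#' `||a_d| - |a_p|| / (0.5 (|a_d| + |a_p|)) < rel_tol`.
#'
#' @param ad,ap N x 3 translated joint accelerations of the distal and
#'   proximal segments (global frame, m/s^2).
#' @param th_max magnitude threshold, m/s^2.
#' @param rel_tol relative magnitude-difference tolerance.
#' @return logical vector, TRUE where the sample is valid.
#' @export
valid_sample_mask <- function(ad, ap, th_max = 6, rel_tol = 0.2) {
  ad <- as_vec3_matrix(ad); ap <- as_vec3_matrix(ap)
  if (nrow(ad) != nrow(ap)) stop("distal and proximal series differ in length")
  nd <- vec3_norm(ad); np <- vec3_norm(ap)
  mean_mag <- 0.5 * (nd + np)
  rel <- ifelse(mean_mag > 0, abs(nd - np) / mean_mag, Inf)
  nd > th_max & np > th_max & rel < rel_tol
}

#' Detect movement-cycle starts
#'
#' A movement cycle (one left plus one right turn) starts at a local maximum
#' of the segment's angular velocity about the global X axis. The series is
#' zero-phase low-passed (default 2 Hz) before peak picking; maxima closer
#' than `min_period` are merged keeping the larger.
#'
#' @param omega_x_global angular velocity about global X, rad/s.
#' @param rate sampling rate, Hz.
#' @param min_period minimum cycle period in seconds (default 1).
#' @param smooth_hz low-pass cutoff for smoothing, Hz.
#' @return integer vector of cycle start indices (at least 2, else an error).
#' @export
detect_cycles <- function(omega_x_global, rate, min_period = 1, smooth_hz = 2) {
  s <- as.numeric(lowpass_cols(matrix(omega_x_global, ncol = 1L), rate, smooth_hz))
  n <- length(s)
  if (n < 3L) stop("series too short for cycle detection")
  if (diff(range(s)) < 1e-6) {
    stop("angular-velocity series is constant: no local maxima to segment movement cycles")
  }
  peaks <- which(s[2:(n - 1L)] >= s[1:(n - 2L)] & s[2:(n - 1L)] > s[3:n]) + 1L
  # ignore numerically flat "maxima" of a near-constant signal
  peaks <- peaks[s[peaks] > min(s) + 1e-9 * max(1, diff(range(s)))]
  if (length(peaks) > 1L) {
    min_gap <- round(min_period * rate)
    keep <- peaks[1L]
    for (p in peaks[-1L]) {
      last <- keep[length(keep)]
      if (p - last >= min_gap) {
        keep <- c(keep, p)
      } else if (s[p] > s[last]) {
        keep[length(keep)] <- p
      }
    }
    peaks <- keep
  }
  if (length(peaks) < 2L) {
    stop("fewer than 2 angular-velocity maxima: cannot segment movement cycles")
  }
  peaks
}

# Window boundaries (sample index ranges) tiling 1..n from cycle starts,
# `window_cycles` cycles per window. Samples before the first and after the
# last cycle start are attached to the first / last window; a trailing stub
# shorter than half the median window is merged into the previous window.
drift_windows <- function(cycle_starts, n, window_cycles = 2L) {
  edges <- cycle_starts[seq(1L, length(cycle_starts), by = window_cycles)]
  edges <- unique(c(1L, edges, n + 1L))
  edges <- sort(edges[edges <= n + 1L])
  starts <- edges[-length(edges)]
  ends <- edges[-1L] - 1L
  ok <- ends >= starts
  starts <- starts[ok]; ends <- ends[ok]
  len <- ends - starts + 1L
  m <- length(starts)
  if (m > 1L && len[m] < stats::median(len) / 2) {
    ends[m - 1L] <- ends[m]
    starts <- starts[-m]; ends <- ends[-m]
  }
  data.frame(start = starts, end = ends, mid = floor((starts + ends) / 2))
}

#' Estimate joint drift over cycle windows
#'
#' For every valid sample the instantaneous drift quaternion `delta(t)` is
#' the minimal rotation taking the distal translated joint acceleration onto
#' the proximal one (both global frame). Per window of `window_cycles`
#' movement cycles the drift estimate is the rotation average of the valid
#' `delta(t)`; windows with too few valid samples to support a trustworthy
#' estimate (fewer than 25 samples or 2% of the window) inherit the
#' previous window's estimate (identity for a first such window). For the azimuth pass
#' (`azimuth = TRUE`) the acceleration components along the vertical axis
#' are zeroed first, validity requires both horizontal magnitudes above
#' `th_azimuth` plus the same relative-difference rule, and the window
#' estimate is reduced to its twist about the vertical axis. The vertical
#' axis is measured per window as the mean direction of the proximal
#' translated acceleration (the gravity reaction): when the orientation
#' estimates are drift-free this is exactly global Y, and when they carry
#' common-mode drift it is the direction that vertical has been dragged to,
#' which keeps gravity out of the horizontal residuals.
#'
#' @param ad,ap N x 3 translated joint accelerations (global frame) of the
#'   distal and proximal segments.
#' @param cycle_starts cycle start indices from [detect_cycles()].
#' @param window_cycles cycles per averaging window (default 2).
#' @param th_max,rel_tol first-pass validity thresholds (see
#'   [valid_sample_mask()]).
#' @param azimuth logical: run the vertical-zeroed azimuth variant.
#' @param th_azimuth horizontal magnitude threshold for the azimuth pass,
#'   m/s^2.
#' @return a `drift_estimate`: list with `windows` (data.frame: start, end,
#'   mid sample indices, quaternion columns qw/qx/qy/qz, angle_deg,
#'   n_valid, frac_valid), `mask` (per-sample validity), and `beta_deg`
#'   (per-sample mismatch angle, NA where invalid).
#' @export
estimate_drift <- function(ad, ap, cycle_starts, window_cycles = 2L,
                           th_max = 6, rel_tol = 0.2,
                           azimuth = FALSE, th_azimuth = 0.6) {
  ad <- as_vec3_matrix(ad); ap <- as_vec3_matrix(ap)
  n <- nrow(ad)
  wins <- drift_windows(cycle_starts, n, window_cycles)
  verticals <- NULL
  if (azimuth) {
    # zero the component along the measured vertical, per window
    verticals <- matrix(0, nrow(wins), 3L)
    for (k in seq_len(nrow(wins))) {
      idx <- wins$start[k]:wins$end[k]
      v <- colMeans(ap[idx, , drop = FALSE])
      vn <- sqrt(sum(v^2))
      v <- if (vn > 1e-9) v / vn else c(0, 1, 0)
      verticals[k, ] <- v
      ad[idx, ] <- ad[idx, , drop = FALSE] -
        (ad[idx, , drop = FALSE] %*% v) %*% t(v)
      ap[idx, ] <- ap[idx, , drop = FALSE] -
        (ap[idx, , drop = FALSE] %*% v) %*% t(v)
    }
    mask <- valid_sample_mask(ad, ap, th_max = th_azimuth, rel_tol = rel_tol)
  } else {
    mask <- valid_sample_mask(ad, ap, th_max = th_max, rel_tol = rel_tol)
  }
  if (!any(mask)) stop("no valid samples for drift estimation in entire trial")
  # instantaneous delta(t) on valid samples
  nd <- vec3_norm(ad); np <- vec3_norm(ap)
  dot <- rowSums(ad * ap) / pmax(nd * np, 1e-300)
  beta <- acos(pmin(1, pmax(-1, dot)))
  cr <- cross3(ad, ap)
  crn <- vec3_norm(cr)
  beta_deg <- ifelse(mask, rad2deg(beta), NA_real_)

  m <- nrow(wins)
  qw <- matrix(rep(c(1, 0, 0, 0), m), m, 4L, byrow = TRUE)
  nvalid <- integer(m)
  prev <- quat_identity()
  for (k in seq_len(m)) {
    idx <- wins$start[k]:wins$end[k]
    v <- idx[mask[idx]]
    # samples where the cross product is defined (non-parallel accelerations)
    vax <- v[crn[v] > 1e-12]
    vid <- v[crn[v] <= 1e-12]
    nvalid[k] <- length(v)
    # too few valid samples -> no trustworthy estimate for this window
    min_valid <- max(25L, ceiling(0.02 * length(idx)))
    if (length(v) < min_valid) {
      qw[k, ] <- prev
    } else {
      if (length(vax) > 0L) {
        axes <- cr[vax, , drop = FALSE] / crn[vax]
        half <- beta[vax] / 2
        dq <- cbind(cos(half), sin(half) * axes)
      } else {
        dq <- NULL
      }
      if (length(vid) > 0L) {
        dq <- rbind(dq, matrix(rep(c(1, 0, 0, 0), length(vid)),
                               ncol = 4L, byrow = TRUE))
      }
      qbar <- quat_mean(dq)
      if (azimuth) qbar <- quat_twist(qbar, verticals[k, ])$quat
      qw[k, ] <- qbar
      prev <- qbar
    }
  }
  wins$qw <- qw[, 1L]; wins$qx <- qw[, 2L]; wins$qy <- qw[, 3L]; wins$qz <- qw[, 4L]
  wins$angle_deg <- rad2deg(quat_angle(qw))
  wins$n_valid <- nvalid
  wins$frac_valid <- nvalid / (wins$end - wins$start + 1L)
  structure(list(windows = wins, mask = mask, beta_deg = beta_deg,
                 azimuth = azimuth),
            class = "drift_estimate")
}

#' Apply a drift estimate to an orientation trace
#'
#' Builds a per-sample correction quaternion by spherical-linear
#' interpolation between consecutive window estimates, anchored at window
#' midpoints (constant extrapolation before the first and after the last
#' midpoint), and left-applies it to the distal segment's orientation. The
#' interpolated correction is continuous, so the corrected trace is too.
#'
#' @param trace [orientation_trace] of the (distal) segment.
#' @param drift a `drift_estimate` from [estimate_drift()].
#' @return the corrected [orientation_trace].
#' @export
correct_orientations <- function(trace, drift) {
  wins <- drift$windows
  n <- nrow(trace$q)
  qwin <- as.matrix(wins[, c("qw", "qx", "qy", "qz")])
  corr <- matrix(0, n, 4L)
  mids <- wins$mid
  m <- length(mids)
  corr[1:mids[1L], ] <- matrix(qwin[1L, ], mids[1L], 4L, byrow = TRUE)
  if (m > 1L) {
    for (k in seq_len(m - 1L)) {
      i0 <- mids[k]; i1 <- mids[k + 1L]
      s <- seq(0, 1, length.out = i1 - i0 + 1L)
      seg <- quat_slerp(qwin[k, ], qwin[k + 1L, ], s)
      corr[i0:i1, ] <- as_quat_matrix(seg)
    }
  }
  if (mids[m] < n) {
    corr[(mids[m] + 1L):n, ] <- matrix(qwin[m, ], n - mids[m], 4L, byrow = TRUE)
  }
  qc <- quat_normalize(.quat_mult_raw(corr, trace$q))
  orientation_trace(trace$t, qc, segment = trace$segment)
}

#' Two-pass joint-drift correction for a segment pair
#'
#' Runs the full correction for one joint: translated joint accelerations
#' are computed from both calibrated streams and the current orientation
#' estimates; movement cycles are detected on the proximal segment's global
#' X angular velocity; a first drift pass (full 3D, gravity-dominated) is
#' estimated and applied to the distal trace; joint accelerations are
#' recomputed and a second, azimuth-only pass (vertical components zeroed)
#' is estimated over the same windows and applied. The correction is applied
#' entirely to the distal segment; process joints from the trunk outwards so
#' the lower back anchors the chain's heading.
#'
#' @param prox_trace,dist_trace [orientation_trace]s from
#'   [strapdown_integrate()].
#' @param prox_stream,dist_stream calibrated [imu_stream]s.
#' @param r_p,r_d sensor-to-joint vectors (anatomical frame, m) of the
#'   proximal and distal sensors.
#' @param th_max,rel_tol,th_azimuth,window_cycles thresholds as in
#'   [estimate_drift()].
#' @param cycle_starts optional precomputed cycle start indices.
#' @return list with `dist_trace` (corrected), `pass1`, `pass2` (the two
#'   `drift_estimate`s) and `cycle_starts`.
#' @export
drift_correct_pair <- function(prox_trace, dist_trace, prox_stream, dist_stream,
                               r_p, r_d, th_max = 6, rel_tol = 0.2,
                               th_azimuth = 0.6, window_cycles = 2L,
                               cycle_starts = NULL) {
  od_p <- gyro_derivative(prox_stream$gyro, prox_stream$rate)
  od_d <- gyro_derivative(dist_stream$gyro, dist_stream$rate)
  ap <- joint_acceleration_global(prox_trace, prox_stream, r_p, od_p)
  ad <- joint_acceleration_global(dist_trace, dist_stream, r_d, od_d)
  if (is.null(cycle_starts)) {
    gyro_sm <- lowpass_cols(prox_stream$gyro, prox_stream$rate, 2)
    omega_g <- quat_rotate(prox_trace$q, gyro_sm)
    cycle_starts <- detect_cycles(omega_g[, 1L], prox_stream$rate)
  }
  pass1 <- estimate_drift(ad, ap, cycle_starts, window_cycles = window_cycles,
                          th_max = th_max, rel_tol = rel_tol)
  dist1 <- correct_orientations(dist_trace, pass1)
  ad1 <- joint_acceleration_global(dist1, dist_stream, r_d, od_d)
  pass2 <- estimate_drift(ad1, ap, cycle_starts, window_cycles = window_cycles,
                          azimuth = TRUE, th_azimuth = th_azimuth,
                          rel_tol = rel_tol)
  dist2 <- correct_orientations(dist1, pass2)
  list(dist_trace = dist2, pass1 = pass1, pass2 = pass2,
       cycle_starts = cycle_starts)
}

#' Azimuth error of an estimated relative orientation
#'
#' Signed rotation error about the global vertical axis of an estimated
#' joint (relative) orientation versus ground truth. The relative error
#' rotation is expressed in the global frame through the true proximal
#' orientation, then reduced to its twist about global Y.
#'
#' @param q_prox_est,q_dist_est estimated orientation traces (N x 4).
#' @param q_prox_true,q_dist_true ground-truth traces.
#' @return numeric vector of signed azimuth errors in degrees.
#' @export
relative_azimuth_error <- function(q_prox_est, q_dist_est,
                                   q_prox_true, q_dist_true) {
  rel_est <- .relative_quats(q_prox_est, q_dist_est)
  rel_true <- .relative_quats(q_prox_true, q_dist_true)
  err <- quat_normalize(.quat_mult_raw(rel_est, quat_conjugate(rel_true)))
  qpt <- as_quat_matrix(q_prox_true)
  err_g <- quat_normalize(.quat_mult_raw(.quat_mult_raw(qpt, err),
                                         quat_conjugate(qpt)))
  rad2deg(quat_twist_angles(err_g, c(0, 1, 0)))
}
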