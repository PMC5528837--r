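#' IMU stream container
#'
#' Per-sensor time series of acceleration (sensor frame, m/s^2) and angular
#' velocity (sensor frame, rad/s), uniformly sampled.
#'
#' @param t timestamps in seconds (uniform; jitter beyond 1e-6 s is an error).
#' @param accel N x 3 accelerometer matrix, m/s^2.
#' @param gyro N x 3 gyroscope matrix, rad/s.
#' @param rate sampling rate in Hz; defaults to `1/median(diff(t))`.
#' @param segment segment label (e.g. `"shank_l"`).
#' @return an `imu_stream` object (list with the validated fields).
#' @export
imu_stream <- function(t, accel, gyro, rate = NULL, segment = "unknown") {
  accel <- as_vec3_matrix(accel); gyro <- as_vec3_matrix(gyro)
  n <- length(t)
  if (nrow(accel) != n || nrow(gyro) != n) {
    stop("t, accel and gyro must have the same number of samples")
  }
  if (n < 2L) stop("an IMU stream needs at least 2 samples")
  if (!all(is.finite(t)) || !all(is.finite(accel)) || !all(is.finite(gyro))) {
    stop("IMU stream contains non-finite values")
  }
  dt <- diff(t)
  if (is.null(rate)) rate <- 1 / stats::median(dt)
  if (!is.finite(rate) || rate <= 0) stop("sampling rate must be positive")
  if (max(abs(dt - 1 / rate)) > 1e-6) {
    bad <- which(abs(dt - 1 / rate) > 1e-6)[1L] + 1L
    stop(sprintf("non-uniform sampling: sample %d deviates from 1/rate by %.3g s",
                 bad, dt[bad - 1L] - 1 / rate))
  }
  structure(list(t = as.numeric(t), accel = accel, gyro = gyro,
                 rate = rate, segment = segment),
            class = "imu_stream")
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream> segment %s: %d samples @ %g Hz (%.2f s)\n",
              x$segment, length(x$t), x$rate, diff(range(x$t))))
  invisible(x)
}

#' Orientation trace container
#'
#' Uniformly sampled unit-quaternion series giving, per sample, the rotation
#' from a segment's anatomical frame to the global frame. The global frame is
#' Y up (aligned with gravity), X forward along the fall line, Z right.
#'
#' @param t timestamps in seconds.
#' @param q N x 4 matrix of unit quaternions (scalar first).
#' @param segment segment label.
#' @return an `orientation_trace` object.
#' @export
orientation_trace <- function(t, q, segment = "unknown") {
  q <- as_quat_matrix(q)
  if (length(t) != nrow(q)) stop("t and q must have the same number of samples")
  .check_unit(q, "orientation trace")
  structure(list(t = as.numeric(t), q = q, segment = segment),
            class = "orientation_trace")
}

#' @export
print.orientation_trace <- function(x, ...) {
  cat(sprintf("<orientation_trace> segment %s: %d samples (%.2f s)\n",
              x$segment, length(x$t), diff(range(x$t))))
  invisible(x)
}

#' Gyroscope offset from the upright posture
#'
#' The constant gyroscope bias is estimated as the per-axis mean over a
#' quasi-static window (the 10 s upright stance of the calibration routine).
#'
#' @param upright an [imu_stream] covering the upright stance.
#' @param min_duration minimum window length in seconds (default 2).
#' @param max_motion_deg_s residual angular rate (after removing the mean)
#'   above which the window is rejected as non-static, degrees/s (default 5).
#' @return estimated offset, 3-vector in rad/s.
#' @export
estimate_gyro_offset <- function(upright, min_duration = 2, max_motion_deg_s = 5) {
  dur <- diff(range(upright$t))
  if (dur < min_duration) {
    stop(sprintf("upright window too short: %.2f s < %.2f s", dur, min_duration))
  }
  offset <- colMeans(upright$gyro)
  resid <- sweep(upright$gyro, 2L, offset)
  peak <- max(vec3_norm(resid))
  if (peak > deg2rad(max_motion_deg_s)) {
    stop(sprintf(paste0("motion detected in upright window: peak residual rate ",
                        "%.1f deg/s exceeds %.1f deg/s"),
                 rad2deg(peak), max_motion_deg_s))
  }
  offset
}

#' Subtract a constant gyroscope offset
#' @param stream an [imu_stream].
#' @param offset 3-vector, rad/s.
#' @return the corrected stream.
#' @export
subtract_gyro_offset <- function(stream, offset) {
  stream$gyro <- sweep(stream$gyro, 2L, offset)
  stream
}

#' Apply a sensor-to-segment calibration to a stream
#'
#' Rotates accelerometer and gyroscope readings from the sensor frame into
#' the segment anatomical frame using a calibration quaternion, after which
#' the stream's "body frame" is the anatomical frame.
#'
#' @param stream an [imu_stream].
#' @param q_cal calibration quaternion (sensor frame to anatomical frame).
#' @return the calibrated stream.
#' @export
apply_calibration <- function(stream, q_cal) {
  stream$accel <- quat_rotate(q_cal, stream$accel)
  stream$gyro <- quat_rotate(q_cal, stream$gyro)
  stream
}

# Zero-phase low-pass filter each column (Butterworth order `order`).
# The signal is extended by odd reflection at both ends before filtering so
# the filter's zero initial conditions do not inject edge transients.
lowpass_cols <- function(x, rate, cutoff_hz, order = 2L) {
  if (cutoff_hz >= rate / 2) return(x)
  x <- as.matrix(x)
  n <- nrow(x)
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  np <- min(n - 1L, ceiling(20 * rate / cutoff_hz))
  out <- apply(x, 2L, function(col) {
    front <- 2 * col[1L] - col[(np + 1L):2L]
    back <- 2 * col[n] - col[(n - 1L):(n - np)]
    y <- as.numeric(signal::filtfilt(bf, c(front, col, back)))
    y[(np + 1L):(np + n)]
  })
  matrix(out, nrow = n)
}

#' Resample an IMU stream to a lower rate
#'
#' Anti-aliased decimation: a zero-phase Butterworth low-pass at 0.4 x the
#' target rate is applied, then the signal is linearly interpolated onto a
#' uniform grid at the target rate (used to bring 500 Hz sensor data to the
#' 100 Hz of an optical reference system).
#'
#' @param stream an [imu_stream].
#' @param target_rate requested rate in Hz; must not exceed the stream rate.
#' @return the resampled stream.
#' @export
resample <- function(stream, target_rate) {
  if (target_rate > stream$rate) {
    stop(sprintf("upsampling requested: target %g Hz > stream %g Hz",
                 target_rate, stream$rate))
  }
  if (abs(target_rate - stream$rate) < 1e-9) return(stream)
  acc <- lowpass_cols(stream$accel, stream$rate, 0.4 * target_rate, order = 4L)
  gyr <- lowpass_cols(stream$gyro, stream$rate, 0.4 * target_rate, order = 4L)
  tnew <- seq(stream$t[1L], stream$t[length(stream$t)], by = 1 / target_rate)
  interp <- function(x) {
    vapply(seq_len(3L),
           function(j) stats::approx(stream$t, x[, j], xout = tnew)$y,
           numeric(length(tnew)))
  }
  imu_stream(tnew, interp(acc), interp(gyr), rate = target_rate,
             segment = stream$segment)
}

#' Resample an angle series to a lower rate
#'
#' Same anti-aliasing scheme as [resample()], for scalar angle traces
#' (degrees) such as the wearable joint angles prior to comparison with a
#' 100 Hz reference.
#'
#' @param t timestamps, seconds.
#' @param x angle series, degrees.
#' @param rate current sampling rate, Hz.
#' @param target_rate requested rate, Hz.
#' @return list with `t` and `x` at the target rate.
#' @export
resample_series <- function(t, x, rate, target_rate) {
  if (target_rate > rate) stop("upsampling requested")
  if (abs(target_rate - rate) < 1e-9) return(list(t = t, x = x))
  xf <- as.numeric(lowpass_cols(matrix(x, ncol = 1L), rate, 0.4 * target_rate,
                                order = 4L))
  tnew <- seq(t[1L], t[length(t)], by = 1 / target_rate)
  list(t = tnew, x = stats::approx(t, xf, xout = tnew)$y)
}
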