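#' End-to-end orientation tracking for a trial
#'
#' Runs the wearable pipeline for all segments of a chain: applies the
#' sensor-to-segment calibrations, estimates each segment's initial
#' orientation from the quasi-static trial start (gravity inclination,
#' common zero azimuth), integrates the gyroscopes, and — unless disabled —
#' applies the two-pass joint-drift correction joint by joint from the
#' trunk outwards, with the lower back anchoring the chain's heading.
#' Movement cycles are detected once on the lower back's global-X angular
#' velocity so all joints share the same averaging windows.
#'
#' @param streams named list of [imu_stream]s (gyro offset already
#'   removed), one per chain segment.
#' @param cals named list of `segment_calibration`s (or a
#'   `calibration_result`).
#' @param chain a `chain_model` providing joint topology and sensor-to-joint
#'   vectors.
#' @param correct apply drift correction (default TRUE; FALSE gives raw
#'   strap-down orientation).
#' @param th_max,rel_tol,th_azimuth,window_cycles drift-correction
#'   thresholds, see [estimate_drift()].
#' @param init_window_s seconds of quasi-static data used for the initial
#'   orientation.
#' @return list with `traces` (named list of [orientation_trace]s), `drift`
#'   (per joint: the two `drift_estimate`s) and `cycle_starts`.
#' @export
track_trial <- function(streams, cals, chain, correct = TRUE,
                        th_max = 6, rel_tol = 0.2, th_azimuth = 0.6,
                        window_cycles = 2L, init_window_s = 1.5) {
  segs <- names(chain$segments)
  missing <- setdiff(segs, names(streams))
  if (length(missing) > 0L) {
    stop(sprintf("missing IMU stream(s): %s", paste(missing, collapse = ", ")))
  }
  calibrated <- list(); traces <- list()
  for (nm in segs) {
    st <- apply_calibration(streams[[nm]], cals[[nm]]$q)
    init <- st$t <= st$t[1L] + init_window_s
    q0 <- initial_orientation(st$accel[init, , drop = FALSE])
    calibrated[[nm]] <- st
    traces[[nm]] <- strapdown_integrate(st, q0)
  }
  drift <- list(); cycle_starts <- NULL
  if (correct) {
    lb <- calibrated$lower_back
    gyro_sm <- lowpass_cols(lb$gyro, lb$rate, 2)
    omega_g <- quat_rotate(traces$lower_back$q, gyro_sm)
    cycle_starts <- detect_cycles(omega_g[, 1L], lb$rate)
    for (jn in names(chain$joints)) {
      j <- chain$joints[[jn]]
      res <- drift_correct_pair(traces[[j$prox]], traces[[j$dist]],
                                calibrated[[j$prox]], calibrated[[j$dist]],
                                j$r_p, j$r_d, th_max = th_max,
                                rel_tol = rel_tol, th_azimuth = th_azimuth,
                                window_cycles = window_cycles,
                                cycle_starts = cycle_starts)
      traces[[j$dist]] <- res$dist_trace
      drift[[jn]] <- res[c("pass1", "pass2")]
    }
  }
  list(traces = traces, drift = drift, cycle_starts = cycle_starts)
}

#' Joint angles for every joint of a chain
#'
#' @param traces named list of [orientation_trace]s (or N x 4 matrices with
#'   a shared time base in `t`).
#' @param chain a `chain_model`.
#' @param side_map optional named character vector mapping joint names to
#'   the `side` argument of [grood_suntay()]; defaults to `"none"`
#'   (unmirrored decomposition, directly comparable to simulator scripts).
#' @return named list of `joint_angle_trace`s.
#' @export
trial_joint_angles <- function(traces, chain, side_map = NULL) {
  out <- list()
  for (jn in names(chain$joints)) {
    j <- chain$joints[[jn]]
    side <- if (!is.null(side_map) && jn %in% names(side_map)) side_map[[jn]] else "none"
    out[[jn]] <- grood_suntay(traces[[j$prox]], traces[[j$dist]],
                              joint = jn, side = side)
  }
  out
}
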