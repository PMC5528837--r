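#' CSV and JSON interfaces
#'
#' All traces are exchanged as plain-text CSV with a small `#`-prefixed
#' metadata header (units and rate declared explicitly) and 12 significant
#' decimal digits, so a write/read round trip reproduces values to the
#' printed precision. Angles are always degrees in files (radians are used
#' internally for quaternion work); timestamps are seconds from trial start.
#'
#' @name skimu-io
NULL

.fmt_num <- function(x) sprintf("%.12g", x)

.write_csv_with_meta <- function(df, path, meta) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# skimu %s v1", meta$kind),
               vapply(setdiff(names(meta), "kind"),
                      function(k) sprintf("# %s: %s", k, meta[[k]]),
                      character(1L))), con)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], .fmt_num)
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
}

.read_csv_with_meta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  list(meta = meta, df = df, n_meta = length(meta_lines))
}

#' Read and write IMU streams as CSV
#'
#' Columns `t, ax, ay, az, gx, gy, gz` with acceleration in m/s^2 and
#' angular velocity in rad/s; rate and segment stored in the metadata
#' header. Reading validates the column set and timestamp uniformity and
#' reports the first offending data row on failure.
#'
#' @param stream an [imu_stream].
#' @param path file path.
#' @return `read_imu_csv()` returns an [imu_stream].
#' @export
write_imu_csv <- function(stream, path) {
  df <- data.frame(t = stream$t,
                   ax = stream$accel[, 1L], ay = stream$accel[, 2L],
                   az = stream$accel[, 3L],
                   gx = stream$gyro[, 1L], gy = stream$gyro[, 2L],
                   gz = stream$gyro[, 3L])
  .write_csv_with_meta(df, path, list(kind = "imu_stream",
                                      segment = stream$segment,
                                      rate_hz = .fmt_num(stream$rate),
                                      units = "t s, accel m/s^2, gyro rad/s"))
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path) {
  r <- .read_csv_with_meta(path)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(r$df))) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(setdiff(need, names(r$df)), collapse = ", ")))
  }
  rate <- if (!is.null(r$meta$rate_hz)) as.numeric(r$meta$rate_hz) else NULL
  t <- r$df$t
  if (length(t) >= 2L) {
    rr <- if (is.null(rate)) 1 / stats::median(diff(t)) else rate
    dev <- abs(diff(t) - 1 / rr)
    if (max(dev) > 1e-6) {
      bad <- which(dev > 1e-6)[1L] + 1L
      stop(sprintf("%s: non-uniform timestamps at data row %d (file line ~%d)",
                   path, bad, bad + r$n_meta + 1L))
    }
  }
  imu_stream(t, as.matrix(r$df[, c("ax", "ay", "az")]),
             as.matrix(r$df[, c("gx", "gy", "gz")]), rate = rate,
             segment = if (is.null(r$meta$segment)) "unknown" else r$meta$segment)
}

#' Read and write orientation traces as CSV
#'
#' Columns `t, qw, qx, qy, qz` (unit quaternions, anatomical to global
#' frame).
#' @param trace an [orientation_trace].
#' @param path file path.
#' @return `read_orientation_csv()` returns an [orientation_trace].
#' @export
write_orientation_csv <- function(trace, path) {
  df <- data.frame(t = trace$t, qw = trace$q[, 1L], qx = trace$q[, 2L],
                   qy = trace$q[, 3L], qz = trace$q[, 4L])
  .write_csv_with_meta(df, path, list(kind = "orientation_trace",
                                      segment = trace$segment,
                                      frame = "global Y-up, X fall-line"))
  invisible(path)
}

#' @rdname write_orientation_csv
#' @export
read_orientation_csv <- function(path) {
  r <- .read_csv_with_meta(path)
  need <- c("t", "qw", "qx", "qy", "qz")
  if (!all(need %in% names(r$df))) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(setdiff(need, names(r$df)), collapse = ", ")))
  }
  orientation_trace(r$df$t,
                    quat_normalize(as.matrix(r$df[, c("qw", "qx", "qy", "qz")])),
                    segment = if (is.null(r$meta$segment)) "unknown" else r$meta$segment)
}

#' Read and write joint-angle traces as CSV
#'
#' Columns `t, flexion, abduction, rotation, gimbal` (degrees; gimbal is a
#' 0/1 flag marking samples near the floating-axis singularity).
#' @param angles a `joint_angle_trace` from [grood_suntay()].
#' @param path file path.
#' @return `read_angles_csv()` returns the angle data.frame with attribute
#'   `joint`.
#' @export
write_angles_csv <- function(angles, path) {
  df <- data.frame(t = angles$t, flexion = angles$flexion,
                   abduction = angles$abduction, rotation = angles$rotation,
                   gimbal = as.integer(angles$gimbal))
  .write_csv_with_meta(df, path, list(kind = "joint_angle_trace",
                                      joint = attr(angles, "joint"),
                                      units = "deg"))
  invisible(path)
}

#' @rdname write_angles_csv
#' @export
read_angles_csv <- function(path) {
  r <- .read_csv_with_meta(path)
  need <- c("t", "flexion", "abduction", "rotation")
  if (!all(need %in% names(r$df))) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(setdiff(need, names(r$df)), collapse = ", ")))
  }
  df <- r$df
  df$gimbal <- if ("gimbal" %in% names(df)) df$gimbal == 1 else FALSE
  attr(df, "joint") <- if (is.null(r$meta$joint)) "joint" else r$meta$joint
  df
}

#' Serialise calibration results to JSON
#'
#' Stores each segment's calibration quaternion and its numeric diagnostics
#' (function-valued diagnostics such as objective closures are dropped).
#' @param cals a `calibration_result` or named list of
#'   `segment_calibration`s.
#' @param path file path.
#' @return `read_calibration_json()` returns a named list of
#'   `segment_calibration`s.
#' @export
write_calibration_json <- function(cals, path) {
  out <- lapply(cals, function(cal) {
    diag <- cal$diagnostics
    diag <- diag[vapply(diag, is.numeric, logical(1L))]
    list(q = as.numeric(cal$q), diagnostics = diag)
  })
  ref <- attr(cals, "refinement")
  if (!is.null(ref)) out$`_refinement` <- ref
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("calibration file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- raw$`_refinement`
  raw$`_refinement` <- NULL
  cals <- lapply(raw, function(x) {
    .new_calibration(quat_normalize(as.numeric(x$q)), as.list(x$diagnostics))
  })
  attr(cals, "refinement") <- ref
  class(cals) <- c("calibration_result", class(cals))
  cals
}

#' Default trial configuration
#'
#' Thresholds of the drift correction (magnitude threshold 6 m/s^2,
#' relative-difference tolerance 0.2, azimuth-pass horizontal threshold
#' 0.6 m/s^2, two-cycle averaging windows), default chain geometry, and
#' simulation parameters, as a nested list ready to serialise with
#' [write_config()].
#'
#' @return a nested configuration list.
#' @export
default_config <- function() {
  chain <- ski_chain()
  list(
    rate_hz = 500,
    duration_s = 120,
    turn_period_s = 4,
    seed = 1,
    thresholds = list(th_max = 6, rel_tol = 0.2, th_azimuth = 0.6,
                      window_cycles = 2),
    noise = list(gyro_bias_deg_s = 0.25, gyro_noise_sd_deg_s = 0.2,
                 accel_noise_sd = 0.05),
    geometry = lapply(chain$joints, function(j) {
      list(prox = j$prox, dist = j$dist, r_p = j$r_p, r_d = j$r_d)
    }),
    files = list()
  )
}

#' Read / write a configuration file (YAML)
#' @param config a configuration list.
#' @param path file path.
#' @return `read_config()` returns the configuration list, with defaults
#'   filled in for missing threshold entries.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  def <- default_config()
  for (k in names(def$thresholds)) {
    if (is.null(cfg$thresholds[[k]])) cfg$thresholds[[k]] <- def$thresholds[[k]]
  }
  th <- cfg$thresholds
  if (any(unlist(th[c("th_max", "rel_tol", "th_azimuth", "window_cycles")]) <= 0)) {
    stop("thresholds must be positive")
  }
  cfg
}

# Chain model rebuilt from a config's geometry block.
chain_from_config <- function(cfg) {
  chain <- ski_chain()
  if (!is.null(cfg$geometry)) {
    for (jn in names(cfg$geometry)) {
      g <- cfg$geometry[[jn]]
      chain$joints[[jn]]$r_p <- as.numeric(g$r_p)
      chain$joints[[jn]]$r_d <- as.numeric(g$r_d)
    }
  }
  chain
}
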