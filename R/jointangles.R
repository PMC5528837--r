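#' Grood-Suntay joint coordinate system
#'
#' The relative orientation of a distal segment with respect to its proximal
#' segment is decomposed into three clinically meaningful angles using the
#' floating-axis (joint coordinate system) convention:
#'
#' * flexion about the proximal segment's medio-lateral axis (anatomical Z),
#' * internal/external rotation about the distal segment's longitudinal axis
#'   (anatomical Y),
#' * ab/adduction about the mutually orthogonal floating axis.
#'
#' Segment anatomical frames are X anterior, Y superior, Z right
#' (medio-lateral). With that layout the decomposition is the intrinsic
#' Z-X'-Y'' Euler factorisation of the relative rotation
#' `R_rel = R_prox^T R_dist = Rz(flexion) Rx(abduction) Ry(rotation)`.
#'
#' @name grood-suntay
NULL

# Relative quaternions distal-w.r.t.-proximal, one per row.
.relative_quats <- function(q_prox, q_dist) {
  qp <- as_quat_matrix(q_prox); qd <- as_quat_matrix(q_dist)
  if (nrow(qp) != nrow(qd)) stop("proximal and distal traces differ in length")
  quat_normalize(.quat_mult_raw(as_quat_matrix(quat_conjugate(qp)), qd))
}

#' Compose joint angles into a relative rotation
#'
#' Inverse of [jcs_decompose()]: builds the relative orientation quaternion
#' from flexion/abduction/rotation angles. Used by the simulator so that
#' scripted angles are exactly recoverable.
#'
#' @param flexion,abduction,rotation angles in degrees (scalars or equal
#'   length vectors).
#' @param convention `"zxy"` (limb joints, flexion first) or `"yxz"`
#'   (axial-first alternative for the trunk).
#' @return N x 4 matrix of unit quaternions (vector for scalar input).
#' @export
jcs_compose <- function(flexion, abduction, rotation, convention = c("zxy", "yxz")) {
  convention <- match.arg(convention)
  n <- max(length(flexion), length(abduction), length(rotation))
  f <- deg2rad(rep_len(flexion, n)); a <- deg2rad(rep_len(abduction, n))
  r <- deg2rad(rep_len(rotation, n))
  qz <- cbind(cos(f / 2), 0, 0, sin(f / 2))
  qx <- cbind(cos(a / 2), sin(a / 2), 0, 0)
  qy <- cbind(cos(r / 2), 0, sin(r / 2), 0)
  out <- if (convention == "zxy") {
    .quat_mult_raw(.quat_mult_raw(qz, qx), qy)
  } else {
    .quat_mult_raw(.quat_mult_raw(qy, qx), qz)
  }
  .shape_like(quat_normalize(out), n == 1L)
}

#' Decompose a relative rotation into joint angles
#'
#' @param q_rel relative quaternion(s) (distal w.r.t. proximal), length-4
#'   vector or N x 4 matrix.
#' @inheritParams jcs_compose
#' @return data.frame with columns `flexion`, `abduction`, `rotation`
#'   (degrees) and `gimbal` (TRUE where the abduction angle is within 1
#'   degree of +/-90, where the decomposition degenerates).
#' @export
jcs_decompose <- function(q_rel, convention = c("zxy", "yxz")) {
  convention <- match.arg(convention)
  qm <- as_quat_matrix(q_rel)
  w <- qm[, 1L]; x <- qm[, 2L]; y <- qm[, 3L]; z <- qm[, 4L]
  # rotation matrix entries needed from the quaternion
  m12 <- 2 * (x * y - w * z); m22 <- 1 - 2 * (x^2 + z^2)
  m32 <- 2 * (y * z + w * x)
  m31 <- 2 * (x * z - w * y); m33 <- 1 - 2 * (x^2 + y^2)
  m13 <- 2 * (x * z + w * y); m23 <- 2 * (y * z - w * x)
  m21 <- 2 * (x * y + w * z)
  if (convention == "zxy") {
    # R = Rz(f) Rx(a) Ry(r): sin(a) = m32
    a <- asin(pmin(1, pmax(-1, m32)))
    f <- atan2(-m12, m22)
    r <- atan2(-m31, m33)
  } else {
    # R = Ry(r) Rx(a) Rz(f): sin(a) = -m23
    a <- asin(pmin(1, pmax(-1, -m23)))
    r <- atan2(m13, m33)
    f <- atan2(m21, m22)
  }
  gimbal <- abs(abs(a) - pi / 2) < deg2rad(1)
  data.frame(flexion = rad2deg(f), abduction = rad2deg(a),
             rotation = rad2deg(r), gimbal = gimbal)
}

#' Unwrap a degree series to remove +/-360 jumps
#' @param x numeric vector of angles in degrees.
#' @return unwrapped series (continuous, same start value).
#' @export
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  jump <- round(d / 360)
  x - c(0, cumsum(jump)) * 360
}

#' 3D joint angles from adjacent segment orientations
#'
#' Computes flexion, ab/adduction and internal/external rotation per
#' Grood-Suntay from time-synchronised proximal and distal orientation
#' traces. For left-side joints the ab/adduction and rotation angles are
#' mirrored (sign-flipped) so that the clinical sign convention matches the
#' right side; flexion is side-independent.
#'
#' @param prox,dist [orientation_trace] objects (or N x 4 quaternion
#'   matrices sharing the same sampling).
#' @param joint label stored in the output (e.g. `"knee_l"`).
#' @param side `"right"`, `"left"` (mirrors abduction/rotation) or `"none"`
#'   (raw decomposition, used for round trips against scripted angles).
#' @param convention passed to [jcs_decompose()].
#' @return a `joint_angle_trace`: data.frame with `t`, `flexion`,
#'   `abduction`, `rotation` (degrees, unwrapped) and `gimbal` flag, with
#'   attributes `joint` and `rate`.
#' @export
grood_suntay <- function(prox, dist, joint = "joint", side = c("none", "right", "left"),
                         convention = c("zxy", "yxz")) {
  side <- match.arg(side)
  convention <- match.arg(convention)
  tp <- if (inherits(prox, "orientation_trace")) prox$t else NULL
  qp <- if (inherits(prox, "orientation_trace")) prox$q else prox
  qd <- if (inherits(dist, "orientation_trace")) dist$q else dist
  rel <- .relative_quats(qp, qd)
  ang <- jcs_decompose(rel, convention = convention)
  if (side == "left") {
    ang$abduction <- -ang$abduction
    ang$rotation <- -ang$rotation
  }
  ang$flexion <- unwrap_deg(ang$flexion)
  ang$abduction <- unwrap_deg(ang$abduction)
  ang$rotation <- unwrap_deg(ang$rotation)
  out <- cbind(data.frame(t = if (is.null(tp)) seq_len(nrow(ang)) else tp), ang)
  attr(out, "joint") <- joint
  class(out) <- c("joint_angle_trace", class(out))
  out
}

#' Trunk angles (lower back vs sternum/upper back)
#'
#' Same floating-axis decomposition applied to the lower back (proximal) and
#' sternum or upper back (distal) orientations. For this axial joint the
#' default keeps the limb convention (flexion about the lower back's
#' medio-lateral axis, axial rotation about the distal longitudinal axis);
#' `convention = "yxz"` resolves the axial rotation first instead. No
#' left/right mirroring applies.
#'
#' @inheritParams grood_suntay
#' @export
trunk_angles <- function(prox, dist, joint = "trunk", convention = c("zxy", "yxz")) {
  grood_suntay(prox, dist, joint = joint, side = "none",
               convention = match.arg(convention))
}
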