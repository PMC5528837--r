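#' Quaternion and rotation primitives
#'
#' All rotations in skimu are carried by unit quaternions stored scalar-first
#' as `c(w, x, y, z)` (Hamilton convention). A quaternion `q` represents the
#' rotation taking body-frame coordinates to world coordinates via
#' `v_world = q (0, v_body) q*`, so [quat_multiply()] composes rotations in
#' the usual operator order: `quat_rotate(quat_multiply(q1, q2), v)` equals
#' `quat_rotate(q1, quat_rotate(q2, v))` (q2 applied first).
#'
#' Time series of orientations are N x 4 numeric matrices with one quaternion
#' per row; every scalar operation below is vectorised over rows.
#'
#' Because `q` and `-q` encode the same rotation, [quat_canonical()] picks the
#' representative with non-negative scalar part. Canonicalisation is applied
#' only at API boundaries, never inside integration or interpolation loops
#' where sign flips would corrupt continuity.
#'
#' @name quaternions
NULL

.QUAT_NORM_TOL <- 1e-6

#' @rdname quaternions
#' @param w,x,y,z quaternion components (scalar first).
#' @return `quat()` returns a unit-normalised length-4 numeric vector.
#' @export
quat <- function(w, x, y, z) {
  quat_normalize(c(w, x, y, z))
}

#' Identity quaternion
#' @return the length-4 identity rotation `c(1, 0, 0, 0)`.
#' @export
quat_identity <- function() c(1, 0, 0, 0)

# Coerce a length-4 vector or N x 4 matrix to matrix form.
as_quat_matrix <- function(q) {
  if (is.matrix(q)) {
    if (ncol(q) != 4L) stop("quaternion matrix must have 4 columns")
    q
  } else {
    if (length(q) != 4L) stop("a quaternion has 4 components (w, x, y, z)")
    matrix(q, nrow = 1L)
  }
}

as_vec3_matrix <- function(v) {
  if (is.matrix(v)) {
    if (ncol(v) != 3L) stop("3-vector matrix must have 3 columns")
    v
  } else {
    if (length(v) != 3L) stop("expected a 3-vector")
    matrix(v, nrow = 1L)
  }
}

# Return in the same shape (vector vs matrix) as the widest input.
.shape_like <- function(m, template_is_vector) {
  if (template_is_vector && nrow(m) == 1L) drop(m) else m
}

#' Quaternion norms
#' @param q quaternion (length-4 vector) or N x 4 matrix of quaternions.
#' @return numeric vector of Euclidean norms, one per quaternion.
#' @export
quat_norm <- function(q) {
  qm <- as_quat_matrix(q)
  sqrt(rowSums(qm^2))
}

#' Normalise quaternions to unit norm
#' @inheritParams quat_norm
#' @return quaternions rescaled to unit norm, same shape as input.
#' @export
quat_normalize <- function(q) {
  vec <- !is.matrix(q)
  qm <- as_quat_matrix(q)
  n <- sqrt(rowSums(qm^2))
  if (any(!is.finite(n)) || any(n < 1e-300)) {
    stop("cannot normalise a zero or non-finite quaternion")
  }
  .shape_like(qm / n, vec)
}

.check_unit <- function(q, what = "quaternion") {
  n <- quat_norm(q)
  if (any(abs(n - 1) > .QUAT_NORM_TOL)) {
    stop(sprintf("%s must have unit norm (worst deviation %.3g)",
                 what, max(abs(n - 1))))
  }
  invisible(q)
}

#' Canonical sign: non-negative scalar part
#'
#' `q` and `-q` represent the same rotation; this picks the representative
#' with `w >= 0` (ties broken towards the first non-zero component positive).
#' @inheritParams quat_norm
#' @return quaternions with canonical sign, same shape as input.
#' @export
quat_canonical <- function(q) {
  vec <- !is.matrix(q)
  qm <- as_quat_matrix(q)
  s <- sign(qm[, 1L])
  zero <- s == 0
  if (any(zero)) {
    # w == 0: first non-zero of (x, y, z) decides
    for (j in 2:4) {
      idx <- zero & s == 0
      s[idx] <- sign(qm[idx, j])
    }
    s[s == 0] <- 1
  }
  .shape_like(qm * s, vec)
}

#' Hamilton product of unit quaternions
#'
#' Rows are recycled if one argument has a single quaternion. Inputs are
#' validated to unit norm; the product is renormalised so norm stays within
#' 1e-9 of 1 over arbitrarily long composition chains.
#'
#' @param q1,q2 quaternions (length-4 vectors or N x 4 matrices).
#' @return the composed rotation(s) `q1 (x) q2` (q2 applied first).
#' @export
quat_multiply <- function(q1, q2) {
  vec <- !is.matrix(q1) && !is.matrix(q2)
  a <- as_quat_matrix(q1); b <- as_quat_matrix(q2)
  .check_unit(a); .check_unit(b)
  .shape_like(quat_normalize(.quat_mult_raw(a, b)), vec)
}

# Hamilton product without validation/normalisation (internal hot path).
.quat_mult_raw <- function(a, b) {
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  w1 <- a[, 1L]; x1 <- a[, 2L]; y1 <- a[, 3L]; z1 <- a[, 4L]
  w2 <- b[, 1L]; x2 <- b[, 2L]; y2 <- b[, 3L]; z2 <- b[, 4L]
  cbind(w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
        w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
        w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
        w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2,
        deparse.level = 0L)
}

#' Quaternion conjugate / inverse
#' @inheritParams quat_norm
#' @return for unit quaternions the conjugate equals the inverse rotation.
#' @export
quat_conjugate <- function(q) {
  vec <- !is.matrix(q)
  qm <- as_quat_matrix(q)
  .shape_like(cbind(qm[, 1L], -qm[, 2L], -qm[, 3L], -qm[, 4L],
                    deparse.level = 0L), vec)
}

#' @rdname quat_conjugate
#' @export
quat_inverse <- function(q) quat_conjugate(.check_unit(q))

#' Rotate 3-vectors by quaternions
#'
#' Applies `v' = q (0, v) q*`. Both arguments are vectorised over rows and
#' recycled against each other.
#' @param q unit quaternion(s).
#' @param v 3-vector or N x 3 matrix of vectors.
#' @return rotated vector(s), same shape as `v` (matrix if either input has
#'   multiple rows).
#' @export
quat_rotate <- function(q, v) {
  vec <- !is.matrix(v) && !is.matrix(q)
  qm <- as_quat_matrix(q); vm <- as_vec3_matrix(v)
  if (nrow(qm) == 1L && nrow(vm) > 1L) qm <- qm[rep(1L, nrow(vm)), , drop = FALSE]
  if (nrow(vm) == 1L && nrow(qm) > 1L) vm <- vm[rep(1L, nrow(qm)), , drop = FALSE]
  w <- qm[, 1L]; u <- qm[, 2:4, drop = FALSE]
  # v' = v + 2 u x (u x v + w v)
  tmp <- cross3(u, vm) + w * vm
  .shape_like(vm + 2 * cross3(u, tmp), vec)
}

#' Row-wise cross product of 3-vectors
#' @param a,b N x 3 matrices (or length-3 vectors); recycled against each other.
#' @return N x 3 matrix (or length-3 vector) of cross products `a x b`.
#' @export
cross3 <- function(a, b) {
  vec <- !is.matrix(a) && !is.matrix(b)
  am <- as_vec3_matrix(a); bm <- as_vec3_matrix(b)
  if (nrow(am) == 1L && nrow(bm) > 1L) am <- am[rep(1L, nrow(bm)), , drop = FALSE]
  if (nrow(bm) == 1L && nrow(am) > 1L) bm <- bm[rep(1L, nrow(am)), , drop = FALSE]
  .shape_like(cbind(am[, 2L] * bm[, 3L] - am[, 3L] * bm[, 2L],
                    am[, 3L] * bm[, 1L] - am[, 1L] * bm[, 3L],
                    am[, 1L] * bm[, 2L] - am[, 2L] * bm[, 1L],
                    deparse.level = 0L), vec)
}

vec3_norm <- function(v) {
  vm <- as_vec3_matrix(v)
  sqrt(rowSums(vm^2))
}

vec3_normalize <- function(v) {
  vec <- !is.matrix(v)
  vm <- as_vec3_matrix(v)
  n <- vec3_norm(vm)
  if (any(n < 1e-300)) stop("cannot normalise a zero vector")
  .shape_like(vm / n, vec)
}

#' Axis-angle construction and extraction
#'
#' `quat_from_axis_angle()` builds `[cos(angle/2), sin(angle/2) * axis]`;
#' `axis_angle_of()` inverts it with the angle folded into `[0, pi]`.
#' The round trip reproduces the quaternion up to the q/-q sign ambiguity.
#'
#' @param axis unit 3-vector (checked to norm 1 within 1e-9 unless angle is 0).
#' @param angle rotation angle in radians.
#' @return `quat_from_axis_angle()`: a unit quaternion. `axis_angle_of()`: a
#'   list with elements `axis` (unit 3-vector) and `angle` (radians in
#'   `[0, pi]`); for the identity rotation the axis is arbitrary `(1, 0, 0)`.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  if (length(angle) != 1L || !is.finite(angle)) stop("angle must be a finite scalar")
  if (angle == 0) return(quat_identity())
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("zero axis with non-zero angle")
  if (abs(n - 1) > 1e-9) stop("axis must be a unit vector")
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

#' @rdname quat_from_axis_angle
#' @param q a unit quaternion.
#' @export
axis_angle_of <- function(q) {
  .check_unit(q)
  q <- quat_canonical(q)
  s <- sqrt(sum(q[2:4]^2))
  if (s < 1e-12) return(list(axis = c(1, 0, 0), angle = 0))
  list(axis = q[2:4] / s, angle = 2 * atan2(s, q[1L]))
}

#' Rotation angle of quaternions
#' @inheritParams quat_norm
#' @return rotation angle(s) in radians, in `[0, pi]`.
#' @export
quat_angle <- function(q) {
  qm <- as_quat_matrix(q)
  2 * acos(pmin(1, abs(qm[, 1L])))
}

#' Minimal rotation between two vectors
#'
#' Returns the unit quaternion rotating the direction of `v1` onto the
#' direction of `v2`: the angle is `acos` of the normalised dot product and
#' the axis the normalised cross product. For (near-)antiparallel inputs the
#' cross product vanishes and the axis is chosen deterministically as the
#' normalised component, orthogonal to `v1`, of the global basis vector along
#' which `v1` is smallest in magnitude.
#'
#' @param v1,v2 non-zero 3-vectors.
#' @return unit quaternion `q` with `quat_rotate(q, v1/|v1|) == v2/|v2|`.
#' @export
quat_between_vectors <- function(v1, v2) {
  a <- vec3_normalize(v1); b <- vec3_normalize(v2)
  d <- sum(a * b)
  cr <- cross3(a, b)
  s <- sqrt(sum(cr^2))
  if (s < 1e-9) {
    if (d > 0) return(quat_identity())
    # antiparallel: deterministic orthogonal axis (smallest-component rule)
    e <- c(0, 0, 0); e[which.min(abs(a))] <- 1
    axis <- vec3_normalize(e - sum(e * a) * a)
    return(quat_from_axis_angle(axis, pi))
  }
  angle <- atan2(s, d)
  quat_from_axis_angle(cr / s, angle)
}

#' Convert between quaternions and 3 x 3 rotation matrices
#' @param q a unit quaternion.
#' @return `quat_to_matrix()`: the 3 x 3 rotation matrix `R` with
#'   `R %*% v == quat_rotate(q, v)`.
#' @export
quat_to_matrix <- function(q) {
  .check_unit(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3L, byrow = TRUE)
}

#' @rdname quat_to_matrix
#' @param R a 3 x 3 rotation matrix (orthonormal, det +1).
#' @return `quat_from_matrix()`: the corresponding unit quaternion with
#'   canonical sign.
#' @export
quat_from_matrix <- function(R) {
  if (!is.matrix(R) || any(dim(R) != 3L)) stop("R must be a 3 x 3 matrix")
  if (abs(det(R) - 1) > 1e-6 || max(abs(crossprod(R) - diag(3))) > 1e-6) {
    stop("R is not a rotation matrix")
  }
  # Shepperd's method: pick the numerically largest component first
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr >= max(diag(R))) {
    w <- sqrt(1 + tr) / 2
    q <- c(w,
           (R[3, 2] - R[2, 3]) / (4 * w),
           (R[1, 3] - R[3, 1]) / (4 * w),
           (R[2, 1] - R[1, 2]) / (4 * w))
  } else {
    i <- which.max(diag(R))
    j <- (i %% 3L) + 1L; k <- (j %% 3L) + 1L
    s <- sqrt(1 + R[i, i] - R[j, j] - R[k, k]) * 2
    v <- numeric(3)
    v[i] <- s / 4
    v[j] <- (R[j, i] + R[i, j]) / s
    v[k] <- (R[k, i] + R[i, k]) / s
    q <- c((R[k, j] - R[j, k]) / s, v)
  }
  quat_canonical(quat_normalize(q))
}

#' Exponential and logarithmic maps
#'
#' `quat_exp_vec()` maps rotation vectors (axis * angle, radians) to unit
#' quaternions; `quat_log_vec()` is its inverse. Both are vectorised over
#' rows and numerically safe near the identity.
#'
#' @param v rotation vector(s): length-3 vector or N x 3 matrix.
#' @return `quat_exp_vec()`: unit quaternion(s); `quat_log_vec()`: rotation
#'   vector(s).
#' @export
quat_exp_vec <- function(v) {
  vec <- !is.matrix(v)
  vm <- as_vec3_matrix(v)
  th <- sqrt(rowSums(vm^2))
  half <- th / 2
  # sin(th/2)/th with series fallback for small angles
  k <- ifelse(th > 1e-8, sin(half) / pmax(th, 1e-300), 0.5 - th^2 / 48)
  .shape_like(cbind(cos(half), vm * k, deparse.level = 0L), vec)
}

#' @rdname quat_exp_vec
#' @param q unit quaternion(s).
#' @export
quat_log_vec <- function(q) {
  vec <- !is.matrix(q)
  qm <- as_quat_matrix(q)
  # work on the w >= 0 representative so the angle is in [0, pi]
  s <- ifelse(qm[, 1L] < 0, -1, 1)
  qm <- qm * s
  sn <- sqrt(rowSums(qm[, 2:4, drop = FALSE]^2))
  th <- 2 * atan2(sn, qm[, 1L])
  k <- ifelse(sn > 1e-12, th / pmax(sn, 1e-300), 2)
  .shape_like(qm[, 2:4, drop = FALSE] * k, vec)
}

#' Spherical linear interpolation
#'
#' Interpolates along the shortest geodesic from `q1` (`s = 0`) to `q2`
#' (`s = 1`); `s` may be a vector, giving one quaternion per element.
#' @param q1,q2 unit quaternions.
#' @param s interpolation parameter(s) in `[0, 1]` (values outside
#'   extrapolate along the same geodesic).
#' @return N x 4 matrix of interpolated unit quaternions (vector if
#'   `length(s) == 1`).
#' @export
quat_slerp <- function(q1, q2, s) {
  .check_unit(q1); .check_unit(q2)
  # relative rotation, shortest path
  rel <- .quat_mult_raw(as_quat_matrix(quat_conjugate(q1)), as_quat_matrix(q2))
  rel <- quat_normalize(drop(rel))
  if (rel[1L] < 0) rel <- -rel
  rv <- quat_log_vec(rel)
  out <- quat_exp_vec(outer(s, rv))
  outm <- as_quat_matrix(out)
  res <- quat_normalize(.quat_mult_raw(as_quat_matrix(q1), outm))
  .shape_like(as_quat_matrix(res), length(s) == 1L)
}

#' Rotation average of quaternions
#'
#' Computes the chordal-L2 mean: the principal eigenvector of the weighted
#' outer-product sum of the quaternions after sign alignment to the first.
#' This is the standard rotation-averaging estimator and is invariant to the
#' q/-q ambiguity of each input.
#'
#' @param q N x 4 matrix of unit quaternions (N >= 1).
#' @param weights optional non-negative weights, recycled to N rows.
#' @return the mean unit quaternion (canonical sign).
#' @export
quat_mean <- function(q, weights = NULL) {
  qm <- as_quat_matrix(q)
  .check_unit(qm)
  if (is.null(weights)) weights <- rep(1, nrow(qm))
  if (length(weights) != nrow(qm)) stop("weights length must match quaternion count")
  if (any(weights < 0)) stop("weights must be non-negative")
  # sign-align to the first quaternion to keep the outer-product sum coherent
  s <- sign(qm %*% qm[1L, ])
  s[s == 0] <- 1
  qa <- qm * drop(s)
  M <- crossprod(qa * sqrt(weights))
  quat_canonical(quat_normalize(eigen(M, symmetric = TRUE)$vectors[, 1L]))
}

#' Twist component of a rotation about a fixed axis
#'
#' Swing-twist decomposition: returns the rotation about `axis` such that
#' `q = swing (x) twist` with the swing axis orthogonal to `axis`. Used to
#' isolate the azimuth (heading) part of a drift estimate.
#'
#' @param q a unit quaternion.
#' @param axis unit 3-vector defining the twist axis.
#' @return list with `quat` (the twist rotation) and `angle` (signed twist
#'   angle in radians, in `(-pi, pi]`, positive per the right-hand rule about
#'   `axis`).
#' @export
quat_twist <- function(q, axis = c(0, 1, 0)) {
  .check_unit(q)
  axis <- vec3_normalize(axis)
  p <- sum(q[2:4] * axis)
  tw <- c(q[1L], p * axis)
  n <- sqrt(sum(tw^2))
  if (n < 1e-12) {
    # pure swing of 180 degrees: twist undefined, return identity
    return(list(quat = quat_identity(), angle = 0))
  }
  tw <- tw / n
  ang <- 2 * atan2(p / n, tw[1L])
  if (ang > pi) ang <- ang - 2 * pi
  if (ang <= -pi) ang <- ang + 2 * pi
  list(quat = tw, angle = ang)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Signed twist angles (radians) about `axis` for an N x 4 quaternion matrix.
quat_twist_angles <- function(q, axis = c(0, 1, 0)) {
  qm <- as_quat_matrix(q)
  axis <- vec3_normalize(axis)
  p <- qm[, 2:4, drop = FALSE] %*% axis
  ang <- 2 * atan2(drop(p), qm[, 1L])
  # fold to (-pi, pi]
  ang <- ((ang + pi) %% (2 * pi)) - pi
  ang[ang == -pi] <- pi
  ang
}
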