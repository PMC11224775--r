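# Unit quaternions in (w, x, y, z) order represent rotations from the module
# local frame into the world frame. All helpers assume (and preserve) unit
# norm; quat_check() normalizes with a warning above a small deviation.

#' Validate and normalize a quaternion
#'
#' Quaternions are length-4 numeric vectors in \code{(w, x, y, z)} order.
#' Deviations from unit norm above \code{tol} trigger a warning before
#' renormalization; non-finite or zero quaternions are errors.
#'
#' @param q numeric length-4 quaternion \code{(w, x, y, z)}.
#' @param tol norm deviation above which a warning is emitted (default 1e-6).
#' @return the unit-normalized quaternion.
#' @export
quat_check <- function(q, tol = 1e-6) {
  q <- as.numeric(q)
  if (length(q) != 4L || !all(is.finite(q)))
    stop("quaternion must be 4 finite numbers (w, x, y, z)")
  nrm <- sqrt(sum(q^2))
  if (nrm == 0) stop("zero quaternion is not a rotation")
  if (abs(nrm - 1) > tol)
    warning(sprintf("quaternion norm deviates from 1 by %.3g; normalizing",
                    abs(nrm - 1)))
  q / nrm
}

quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Rotate a 3-vector by a unit quaternion
#'
#' @param q unit quaternion \code{(w, x, y, z)}.
#' @param v numeric 3-vector.
#' @return the rotated 3-vector \code{q v q*}.
#' @export
quat_rotate <- function(q, v) {
  # q v q^-1 expanded via the cross-product form (faster than building R)
  u <- q[2:4]
  w <- q[1]
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  v + 2 * w * cr + 2 * c(u[2] * cr[3] - u[3] * cr[2],
                         u[3] * cr[1] - u[1] * cr[3],
                         u[1] * cr[2] - u[2] * cr[1])
}

#' Quaternion from an axis-angle rotation
#'
#' @param axis rotation axis (any nonzero 3-vector; normalized internally).
#' @param angle rotation angle in radians.
#' @return unit quaternion \code{(w, x, y, z)}.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("rotation axis must be nonzero")
  c(cos(angle / 2), sin(angle / 2) * axis / nrm)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Shepperd's method: stable quaternion extraction from a rotation matrix.
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

unit3 <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-15) stop("cannot normalize a near-zero vector")
  v / nrm
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
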