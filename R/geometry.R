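## Rigid-body geometry: unit quaternions, rotation matrices, poses.
## Conventions: quaternions are length-4 numeric c(w, x, y, z), |q| = 1.
## A pose places a solute's reference coordinates x as
##   world = R(q) %*% (x - center) + t
## where `center` is the solute's geometric center in reference coordinates,
## so `t` is the world position of the geometric center.

#' Construct a rigid-body pose
#'
#' A pose is a unit quaternion plus a translation. Applied to a solute, the
#' rotation acts about the solute's geometric center and the translation
#' places that center in the world frame (Angstrom units throughout).
#'
#' @param q numeric(4) quaternion `c(w, x, y, z)`; normalized on input.
#' @param t numeric(3) world position of the solute geometric center, in
#'   Angstroms.
#' @return an object of class `bd_pose`.
#' @export
pose <- function(q = c(1, 0, 0, 0), t = c(0, 0, 0)) {
  stopifnot(length(q) == 4, length(t) == 3, all(is.finite(q)), all(is.finite(t)))
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("quaternion has zero norm")
  structure(list(q = q / n, t = as.numeric(t)), class = "bd_pose")
}

#' @export
print.bd_pose <- function(x, ...) {
  cat(sprintf("<pose> q = (%.4f, %.4f, %.4f, %.4f), t = (%.2f, %.2f, %.2f) A\n",
              x$q[1], x$q[2], x$q[3], x$q[4], x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Rotation matrix of a unit quaternion
#'
#' @param q numeric(4) quaternion `c(w, x, y, z)`.
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Quaternion product
#'
#' Composition `quat_multiply(a, b)` is the rotation b followed by a.
#'
#' @param a,b numeric(4) quaternions `c(w, x, y, z)`.
#' @return numeric(4) product quaternion.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion for a rotation about an axis
#'
#' @param axis numeric(3) rotation axis (any norm).
#' @param angle rotation angle in radians.
#' @return numeric(4) unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis has zero norm")
  u <- axis / n
  c(cos(angle / 2), sin(angle / 2) * u)
}

#' Uniform random unit quaternion
#'
#' Marsaglia/Shoemake draw from the invariant measure on SO(3); uses the
#' current R random number stream.
#'
#' @return numeric(4) unit quaternion.
#' @export
quat_random <- function() {
  u <- stats::runif(3)
  s1 <- sqrt(1 - u[1]); s2 <- sqrt(u[1])
  c(s1 * sin(2 * pi * u[2]), s1 * cos(2 * pi * u[2]),
    s2 * sin(2 * pi * u[3]), s2 * cos(2 * pi * u[3]))
}

## internal: rotate rows of an n x 3 matrix
rotate_rows <- function(xyz, q) {
  xyz %*% t(quat_to_matrix(q))
}

#' World-frame atom coordinates of a solute under a pose
#'
#' Rotates the solute's reference coordinates about its geometric center and
#' translates the center to `pose$t`.
#'
#' @param solute a [solute] object.
#' @param pose a [pose] object (default: identity at the reference position).
#' @return n x 3 matrix of coordinates, Angstroms.
#' @export
atoms_at_pose <- function(solute, pose = NULL) {
  xyz <- as.matrix(solute$atoms[, c("x", "y", "z")])
  ctr <- geometric_center(solute)
  if (is.null(pose)) pose <- pose_identity(solute)
  sweep(rotate_rows(sweep(xyz, 2, ctr), pose$q), 2, pose$t, `+`)
}

#' Identity pose of a solute (reference placement)
#'
#' @param solute a [solute] object.
#' @return a [pose] with no rotation and the translation that reproduces the
#'   reference coordinates.
#' @export
pose_identity <- function(solute) {
  pose(c(1, 0, 0, 0), geometric_center(solute))
}
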