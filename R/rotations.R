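# Rotation-matrix algebra used throughout the pipeline.
#
# Convention: a bone basis is a 3x3 orthonormal matrix whose ROWS are the
# bone's local axes (x, y, z) expressed in the global frame.  The Cardan
# factorization is fixed to intrinsic X-Y-Z: R = Rx(phi) %*% Ry(theta) %*%
# Rz(psi), with phi = flexion/extension (X), theta = abduction/adduction (Y),
# psi = axial rotation (Z).  All user-facing angles are in degrees.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Elementary rotation matrices
#'
#' Rotations about the coordinate axes by an angle in degrees.  `rot_x`
#' rotates about the flexion/extension axis, `rot_y` about the
#' abduction/adduction axis and `rot_z` about the longitudinal (axial
#' rotation) axis of a bone.
#'
#' @param angle_deg rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rot_x <- function(angle_deg) {
  a <- angle_deg * DEG2RAD
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0,
           0, c, -s,
           0, s, c), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @export
rot_y <- function(angle_deg) {
  a <- angle_deg * DEG2RAD
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, s,
           0, 1, 0,
           -s, 0, c), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @export
rot_z <- function(angle_deg) {
  a <- angle_deg * DEG2RAD
  c <- cos(a); s <- sin(a)
  matrix(c(c, -s, 0,
           s, c, 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Compose a rotation matrix from a Cardan angle triple
#'
#' Builds `Rx(phi) %*% Ry(theta) %*% Rz(psi)` — the package-wide intrinsic
#' X-Y-Z factorization.  This is the exact inverse of [cardan_angles()] away
#' from gimbal lock.
#'
#' @param phi flexion/extension angle about X, degrees.
#' @param theta abduction/adduction angle about Y, degrees.
#' @param psi axial rotation angle about Z, degrees.
#' @return A 3x3 rotation matrix.
#' @seealso [cardan_angles()]
#' @export
cardan_matrix <- function(phi, theta, psi) {
  rot_x(phi) %*% rot_y(theta) %*% rot_z(psi)
}

#' Check that a matrix is a proper rotation
#'
#' @param m a 3x3 numeric matrix.
#' @param tol orthonormality tolerance (max abs deviation of `m %*% t(m)`
#'   from identity, and of `det(m)` from 1).
#' @return `TRUE` or `FALSE`.
#' @export
is_rotation <- function(m, tol = 1e-6) {
  is.matrix(m) && all(dim(m) == c(3L, 3L)) && all(is.finite(m)) &&
    max(abs(m %*% t(m) - diag(3))) <= tol && abs(det(m) - 1) <= tol
}

stop_basis <- function(what) {
  stop("degenerate basis: ", what, call. = FALSE)
}

#' Project a raw 3x3 matrix onto the nearest rotation matrix
#'
#' Sensor bases are only approximately orthonormal; this returns the closest
#' proper rotation in the Frobenius/polar-decomposition sense, computed from
#' the singular value decomposition (`U %*% t(V)`).  Idempotent on valid
#' rotations.
#'
#' @param raw a 3x3 numeric matrix with positive determinant.
#' @param tol matrices farther than `tol` (max abs entry of `raw %*% t(raw) -
#'   I`) from orthonormal are rejected as degenerate.  Default 1e-3, the
#'   ingestion tolerance for recorded bases.
#' @return The nearest 3x3 rotation matrix.
#' @export
orthonormalize <- function(raw, tol = 1e-3) {
  if (!is.matrix(raw) || !all(dim(raw) == c(3L, 3L)) || !all(is.finite(raw)))
    stop_basis("expected a finite 3x3 matrix")
  d <- det(raw)
  if (!is.finite(d) || d <= .Machine$double.eps)
    stop_basis(sprintf("determinant %.3g is not positive", d))
  if (max(abs(raw %*% t(raw) - diag(3))) > tol)
    stop_basis(sprintf("matrix is farther than %g from orthonormal", tol))
  s <- svd(raw)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) # cannot occur when det(raw) > 0, kept as a guard
    stop_basis("projection produced an improper rotation")
  r
}

#' Rotation of one basis relative to another
#'
#' For a bone basis recorded at a reference time and at a later time, returns
#' the rotation between the two: `R_ref %*% t(R_now)`.  With `R_ref` the
#' basis at the initial posture t0 and `R_now` the basis at frame i this is
#' the bone's t0-relative rotation.
#'
#' @param r_ref,r_now 3x3 rotation matrices (bases).
#' @return A 3x3 rotation matrix.
#' @export
relative_rotation <- function(r_ref, r_now) {
  if (!is_rotation(r_ref)) stop_basis("r_ref is not a rotation matrix")
  if (!is_rotation(r_now)) stop_basis("r_now is not a rotation matrix")
  r_ref %*% t(r_now)
}

#' Joint rotation from the t0-relative rotations of its two bones
#'
#' Given the t0-relative rotation of the parent bone (e.g. the proximal
#' phalanx) and of the child bone (e.g. the intermediate phalanx), returns
#' `parent_rel %*% t(child_rel)`: the joint's rotation away from the
#' neutral-zero posture, whose Cardan decomposition is the joint angle
#' triple.
#'
#' @param parent_rel,child_rel 3x3 rotation matrices, t0-relative rotations
#'   of the parent and child bone.
#' @return A 3x3 rotation matrix.
#' @export
joint_rotation <- function(parent_rel, child_rel) {
  if (!is_rotation(parent_rel)) stop_basis("parent_rel is not a rotation matrix")
  if (!is_rotation(child_rel)) stop_basis("child_rel is not a rotation matrix")
  parent_rel %*% t(child_rel)
}

#' Extract Cardan angles from a rotation matrix
#'
#' Decomposes `R = Rx(phi) %*% Ry(theta) %*% Rz(psi)` and returns the angles
#' in degrees: `phi` (flexion/extension, X), `theta` (abduction/adduction,
#' Y), `psi` (axial rotation, Z).  `phi`, `psi` lie in (-180, 180], `theta`
#' in [-90, 90].  At gimbal lock (|theta| -> 90 deg) `psi` is set to 0 and
#' the residual rotation is folded into `phi`.
#'
#' @param r a 3x3 rotation matrix.
#' @return Named numeric vector `c(phi, theta, psi)` in degrees.
#' @export
cardan_angles <- function(r) {
  if (!is_rotation(r)) stop_basis("input is not a rotation matrix")
  st <- max(-1, min(1, r[1, 3]))
  if (abs(st) < 1 - 1e-10) {
    theta <- asin(st)
    phi <- atan2(-r[2, 3], r[3, 3])
    psi <- atan2(-r[1, 2], r[1, 1])
  } else {
    # gimbal lock: only phi +/- psi is determined; take psi = 0
    theta <- sign(st) * pi / 2
    psi <- 0
    phi <- sign(st) * atan2(r[2, 1], r[2, 2])
  }
  c(phi = phi * RAD2DEG, theta = theta * RAD2DEG, psi = psi * RAD2DEG)
}

#' Unwrap an angle series
#'
#' Removes +/-360 degree jumps from a sequence of angles so consecutive
#' samples never differ by more than 180 degrees, making the series suitable
#' for B-spline interpolation downstream.
#'
#' @param x numeric vector of angles in degrees.
#' @return Unwrapped numeric vector, same length.
#' @export
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  corr <- cumsum(-360 * round(d / 360))
  x + c(0, corr)
}

# Rodrigues formula: rotation by angle_deg about unit axis (length-3 vector).
axis_angle_matrix <- function(axis, angle_deg) {
  a <- angle_deg * DEG2RAD
  u <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(a) * k + (1 - cos(a)) * (k %*% k)
}
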