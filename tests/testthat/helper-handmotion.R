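# Shared fixtures.  Random rotations are built independently of the package
# (QR of a Gaussian matrix) so they can serve as oracles for the rotation
# algebra under test.

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# independent elementary rotations (degrees), used to compose oracle matrices
oracle_rx <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}
oracle_ry <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}
oracle_rz <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

frob <- function(m) sqrt(sum(m^2))

# max abs angle difference between two angle_sets, over all joints
max_angle_err <- function(a, b) {
  max(mapply(function(x, y) max(abs(x - y)), a$angles, b$angles[names(a$angles)]))
}

# a small recording fixture: PIP-only planar flexion of the index finger
pip_ramp_recording <- function(n = 30, peak = 85, rate = 60,
                               skeleton = default_skeleton()) {
  forward_kinematics(skeleton,
                     list(finger2_pip = seq(0, peak, length.out = n)),
                     frame_rate = rate)
}
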