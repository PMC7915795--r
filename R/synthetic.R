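# Forward-kinematics synthetic generator: the stand-in for the hardware
# sensor.  Produces recordings with known ground-truth joint trajectories —
# the round-trip oracle for the angle-extraction path — plus the fist
# scenario used in the validation experiment and a seeded noise model.

#' Build an angle trajectory set
#'
#' Wraps per-joint n x 3 Cardan matrices (degrees, columns phi/theta/psi)
#' into the trajectory container consumed by [forward_kinematics()].  Joints
#' not present are held at zero.
#'
#' @param skeleton a `hand_skeleton`.
#' @param trajectories named list, per joint name an n x 3 numeric matrix
#'   (or a length-n vector, taken as phi with theta = psi = 0).
#' @param frame_rate frames per second.
#' @return An `angle_set` covering every joint of the skeleton.
#' @export
angle_trajectories <- function(skeleton, trajectories, frame_rate = 60) {
  joints <- joints_of(skeleton)
  unknown <- setdiff(names(trajectories), joints$name)
  if (length(unknown) > 0L)
    stop("unknown joints in trajectories: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  lens <- vapply(trajectories, NROW, integer(1))
  if (length(lens) == 0L)
    stop("at least one trajectory is required", call. = FALSE)
  nf <- unname(lens[1])
  if (any(lens != nf))
    stop("trajectories have mismatched frame counts", call. = FALSE)
  if (nf < 2L) stop("trajectories need >= 2 frames", call. = FALSE)
  angles <- lapply(joints$name, function(jn) {
    tr <- trajectories[[jn]]
    m <- matrix(0, nf, 3, dimnames = list(NULL, c("phi", "theta", "psi")))
    if (!is.null(tr)) {
      if (is.matrix(tr)) m[, ] <- tr else m[, "phi"] <- tr
    }
    if (any(!is.finite(m))) stop("non-finite trajectory for ", jn, call. = FALSE)
    m
  })
  names(angles) <- joints$name
  new_angle_set(joints, angles, frame_rate)
}

#' Forward kinematics: recording from joint-angle trajectories
#'
#' Composes, per frame, each bone's global basis by chaining the parent
#' basis with the joint rotation `Rx(phi) %*% Ry(theta) %*% Rz(psi)`
#' (`basis_child = basis_parent %*% joint_rotation`, row-vector convention),
#' and propagates positions distally along each bone's local Z axis with the
#' skeleton's segment lengths.  With all-zero trajectories every frame
#' equals the neutral-zero reference posture.  This is the exact inverse of
#' [compute_joint_angle_series()] (round trip below 1e-6 degrees,
#' noise-free).
#'
#' @param skeleton a `hand_skeleton`.
#' @param trajectories an `angle_set` (see [angle_trajectories()]) or a
#'   named list accepted by it.
#' @param frame_rate frames per second.
#' @param provenance optional provenance string for the recording header.
#' @return A `hand_recording`.
#' @export
forward_kinematics <- function(skeleton, trajectories, frame_rate = 60,
                               provenance = NULL) {
  validate_skeleton(skeleton)
  if (!inherits(trajectories, "angle_set"))
    trajectories <- angle_trajectories(skeleton, trajectories, frame_rate)
  joints <- trajectories$joints
  thetas <- vapply(trajectories$angles, function(m) max(abs(m[, "theta"])),
                   numeric(1))
  if (any(thetas > 90))
    stop("|theta| > 90 degrees is rejected (gimbal lock)", call. = FALSE)
  b <- skeleton$bones
  nf <- trajectories$frame_count
  joint_of_bone <- stats::setNames(joints$name, joints$child_bone)
  frames <- vector("list", nf)
  for (i in seq_len(nf)) {
    bases <- list(); positions <- list()
    for (k in seq_len(nrow(b))) {
      bn <- b$name[k]; pn <- b$parent[k]
      ja <- trajectories$angles[[joint_of_bone[[bn]]]][i, ]
      jrot <- cardan_matrix(ja[1], ja[2], ja[3])
      if (is.na(pn)) {
        bases[[bn]] <- jrot
        positions[[bn]] <- c(0, 0, 0)
      } else {
        bases[[bn]] <- bases[[pn]] %*% jrot
        positions[[bn]] <- positions[[pn]] +
          b$length_mm[b$name == pn] * bases[[pn]][3, ]
      }
    }
    tips <- lapply(1:5, function(d) {
      dp <- digit_bone(d, "distal")
      positions[[dp]] + b$length_mm[b$name == dp] * bases[[dp]][3, ]
    })
    names(tips) <- as.character(1:5)
    frames[[i]] <- list(time_s = (i - 1) / frame_rate, positions = positions,
                        bases = bases, tips = tips)
  }
  new_recording(skeleton, frames, frame_rate, provenance = provenance)
}

cosine_ease <- function(n) (1 - cos(pi * seq(0, 1, length.out = n))) / 2

#' Fist-closing scenario trajectories
#'
#' The validation motion: an outstretched hand closing to a fist.  All four
#' fingers flex simultaneously with a cosine-eased ramp from 0 to scaled
#' peaks — PIP reaches `peak_flexion`, MCP 0.9x, DIP 0.7x — and the thumb
#' performs an opposition ramp (CMC flexion 0.5x with abduction 0.3x and
#' axial rotation 0.4x, MCP and IP flexion 0.5x).  Deterministic.
#'
#' @param skeleton a `hand_skeleton`.
#' @param n_frames number of frames (>= 2).
#' @param peak_flexion peak PIP flexion in degrees, in (0, 110].
#' @return An `angle_set` of target trajectories.
#' @export
fist_scenario <- function(skeleton, n_frames = 100, peak_flexion = 100) {
  stopifnot(n_frames >= 2)
  if (!(peak_flexion > 0 && peak_flexion <= 110))
    stop("peak_flexion must lie in (0, 110] degrees", call. = FALSE)
  s <- cosine_ease(n_frames)
  tr <- list()
  for (d in 2:5) {
    tr[[sprintf("finger%d_mcp", d)]] <- 0.9 * peak_flexion * s
    tr[[sprintf("finger%d_pip", d)]] <- peak_flexion * s
    tr[[sprintf("finger%d_dip", d)]] <- 0.7 * peak_flexion * s
  }
  cmc <- cbind(phi = 0.5 * peak_flexion * s,
               theta = min(0.3 * peak_flexion, 85) * s,
               psi = 0.4 * peak_flexion * s)
  tr[["finger1_cmc"]] <- cmc
  tr[["finger1_mcp"]] <- 0.5 * peak_flexion * s
  tr[["finger1_ip"]] <- 0.5 * peak_flexion * s
  angle_trajectories(skeleton, tr)
}

#' Noise specification for synthetic recordings
#'
#' @param orientation_sigma standard deviation (degrees) of the small random
#'   rotation applied to every bone basis in every frame; the perturbation
#'   axis is uniform on the sphere and the angle is `|Normal(0, sigma)|`.
#' @param position_sigma standard deviation (mm) of isotropic Gaussian
#'   jitter on positions and fingertips.
#' @param seed integer seed; identical seeds give identical noise.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(orientation_sigma = 0, position_sigma = 0, seed = 1L) {
  stopifnot(orientation_sigma >= 0, position_sigma >= 0)
  structure(list(orientation_sigma = orientation_sigma,
                 position_sigma = position_sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add seeded sensor noise to a recording
#'
#' Perturbs every bone basis by a small random rotation and jitters all
#' positions (see [noise_spec()]).  Bases are re-orthonormalized after the
#' perturbation.  With both sigmas zero the recording is returned unchanged,
#' bit for bit.  Reproducible: the same spec always yields the same output.
#'
#' @param recording a `hand_recording`.
#' @param spec a `noise_spec`.
#' @return A `hand_recording` with perturbed states.
#' @export
add_noise <- function(recording, spec) {
  if (!inherits(spec, "noise_spec")) stop("expected a noise_spec", call. = FALSE)
  if (spec$orientation_sigma == 0 && spec$position_sigma == 0)
    return(recording)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  bone_names <- recording$skeleton$bones$name
  frames <- recording$frames
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    for (bn in bone_names) {
      if (spec$orientation_sigma > 0) {
        axis <- stats::rnorm(3)
        ang <- abs(stats::rnorm(1, 0, spec$orientation_sigma))
        f$bases[[bn]] <- orthonormalize(
          f$bases[[bn]] %*% axis_angle_matrix(axis, ang), tol = 1e-6)
      }
      if (spec$position_sigma > 0)
        f$positions[[bn]] <- f$positions[[bn]] +
          stats::rnorm(3, 0, spec$position_sigma)
    }
    if (spec$position_sigma > 0) {
      for (d in as.character(1:5))
        f$tips[[d]] <- f$tips[[d]] + stats::rnorm(3, 0, spec$position_sigma)
    }
    frames[[i]] <- f
  }
  new_recording(recording$skeleton, frames, recording$frame_rate,
                provenance = recording$provenance)
}
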