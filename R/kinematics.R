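# Joint-angle extraction: from per-frame bone bases to per-joint Cardan
# angle time series relative to the neutral-zero posture.
#
# Per bone b the t0-relative rotation at frame i is
#     S_b(i) = R_b(t0) %*% t(R_b(ti))
# and per joint (parent bone p, child bone c)
#     Q(i) = S_p(i) %*% t(S_c(i))
# whose Cardan decomposition is the joint angle triple.  The elbow's parent
# frame is the fixed global frame (upper arm assumed stationary), so its
# parent-relative rotation is the identity.

#' Compute joint-angle time series from a recording
#'
#' For every joint of the skeleton and every frame, extracts the Cardan
#' angle triple of the joint rotation relative to the reference posture.
#' By default frame 0 of the recording is the reference t0, so frame 0
#' yields (0, 0, 0) for every joint.  Each angle series is unwrapped
#' (no +/-360 degree jumps between consecutive frames).
#'
#' @param recording a `hand_recording`.
#' @param reference `NULL` (use frame 0) or an explicit reference posture: a
#'   named list of 3x3 bases per bone, or the result of
#'   [reference_posture()].
#' @return Object of class `angle_set`: list with `joints` (the
#'   [joints_of()] table), `angles` (named list, per joint an n x 3 matrix
#'   with columns `phi`, `theta`, `psi` in degrees), `frame_rate`,
#'   `frame_count`.
#' @export
compute_joint_angle_series <- function(recording, reference = NULL) {
  if (!inherits(recording, "hand_recording"))
    stop("expected a hand_recording", call. = FALSE)
  sk <- recording$skeleton
  joints <- joints_of(sk)
  frames <- recording$frames
  nf <- length(frames)
  ref_bases <- if (is.null(reference)) {
    frames[[1]]$bases
  } else if (!is.null(reference$bases)) reference$bases else reference
  missing <- setdiff(sk$bones$name, names(ref_bases))
  if (length(missing) > 0L)
    stop("reference posture missing bones: ",
         paste(missing, collapse = ", "), call. = FALSE)

  # t0-relative rotation of every bone at every frame
  rel <- lapply(sk$bones$name, function(bn) {
    r0 <- ref_bases[[bn]]
    lapply(seq_len(nf), function(i) {
      b <- frames[[i]]$bases[[bn]]
      if (is.null(b))
        stop(sprintf("incomplete frame %d: missing bone state for %s",
                     i - 1L, bn), call. = FALSE)
      relative_rotation(r0, b)
    })
  })
  names(rel) <- sk$bones$name

  angles <- vector("list", nrow(joints))
  names(angles) <- joints$name
  for (j in seq_len(nrow(joints))) {
    pb <- joints$parent_bone[j]
    cb <- joints$child_bone[j]
    m <- matrix(0, nf, 3, dimnames = list(NULL, c("phi", "theta", "psi")))
    for (i in seq_len(nf)) {
      prel <- if (is.na(pb)) diag(3) else rel[[pb]][[i]]
      m[i, ] <- cardan_angles(joint_rotation(prel, rel[[cb]][[i]]))
    }
    m[, "phi"] <- unwrap_deg(m[, "phi"])
    m[, "psi"] <- unwrap_deg(m[, "psi"])
    angles[[j]] <- m
  }
  new_angle_set(joints, angles, recording$frame_rate)
}

new_angle_set <- function(joints, angles, frame_rate) {
  frame_count <- nrow(angles[[1]])
  stopifnot(all(vapply(angles, nrow, integer(1)) == frame_count))
  structure(list(joints = joints, angles = angles,
                 frame_rate = frame_rate, frame_count = frame_count),
            class = "angle_set")
}

#' @export
print.angle_set <- function(x, ...) {
  cat(sprintf("angle_set: %d joints x %d frames at %g Hz\n",
              length(x$angles), x$frame_count, x$frame_rate))
  invisible(x)
}

#' Extract one angle column from an angle set
#'
#' Convenience accessor for a single joint/axis trajectory.
#'
#' @param set an `angle_set`.
#' @param joint joint name, e.g. `"finger2_pip"`.
#' @param axis `"phi"` (flexion), `"theta"` (abduction) or `"psi"`
#'   (rotation).
#' @return Numeric vector, one value per frame, degrees.
#' @export
angle_series <- function(set, joint, axis = c("phi", "theta", "psi")) {
  axis <- match.arg(axis)
  m <- set$angles[[joint]]
  if (is.null(m)) stop("unknown joint: ", joint, call. = FALSE)
  m[, axis]
}
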