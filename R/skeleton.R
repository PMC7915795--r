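# Hand skeleton topology: bone naming, parent links, joint definitions and
# the neutral-zero reference posture.
#
# Bones: forearm (root), hand (carpus/palm), and per digit d in 1..5 the
# chain metacarpal -> proximal -> intermediate -> distal phalanx.  Digit
# numbering: 1 thumb, 2 index, 3 middle, 4 ring, 5 pinky.  The thumb keeps
# the uniform 4-bone chain with a zero-length metacarpal (the sensor's
# internal hand model does the same); its joints are exposed under the
# clinical aliases CMC / MCP / IP.

DIGIT_NAMES <- c("thumb", "index", "middle", "ring", "pinky")
SEGMENT_NAMES <- c("metacarpal", "proximal", "intermediate", "distal")
SEGMENT_ABBREV <- c(metacarpal = "MC", proximal = "PP",
                    intermediate = "IP", distal = "DP")

digit_bone <- function(digit, segment) sprintf("finger%d_%s", digit, segment)

# Default adult segment lengths in mm (scale = 1).  Thumb metacarpal is 0 by
# design; the thumb's "proximal" slot plays the anatomical first metacarpal,
# as in the sensor's internal model.
DEFAULT_LENGTHS_MM <- c(
  forearm = 250, hand = 80,
  finger1_metacarpal = 0, finger1_proximal = 46,
  finger1_intermediate = 32, finger1_distal = 21,
  finger2_metacarpal = 68, finger2_proximal = 40,
  finger2_intermediate = 23, finger2_distal = 19,
  finger3_metacarpal = 64, finger3_proximal = 45,
  finger3_intermediate = 26, finger3_distal = 20,
  finger4_metacarpal = 58, finger4_proximal = 42,
  finger4_intermediate = 25, finger4_distal = 19,
  finger5_metacarpal = 54, finger5_proximal = 33,
  finger5_intermediate = 18, finger5_distal = 17
)

hand_bone_table <- function() {
  name <- c("forearm", "hand")
  parent <- c(NA_character_, "forearm")
  for (d in 1:5) {
    segs <- digit_bone(d, SEGMENT_NAMES)
    name <- c(name, segs)
    parent <- c(parent, "hand", segs[1:3])
  }
  data.frame(name = name, parent = parent, stringsAsFactors = FALSE)
}

#' Build the canonical hand skeleton
#'
#' Returns the full bone hierarchy from forearm to fingertips: forearm
#' (root), hand (carpus/palm) and for each digit the metacarpal, proximal,
#' intermediate and distal phalanx — 22 bones.  Segment lengths are
#' plausible adult values in mm multiplied by `scale`; the thumb metacarpal
#' has length zero (see the package vignette).  The neutral-zero reference
#' posture is the flat outstretched hand with every bone basis equal to the
#' identity, so all joint angles are zero by construction.
#'
#' @param handedness `"right"` or `"left"`.  The left hand mirrors the right
#'   about the sagittal plane: segment lengths are identical, only the sign
#'   convention of abduction/adduction flips (stored as metadata).
#' @param scale uniform scale factor applied to all segment lengths
#'   (dimensionless, > 0).
#' @return An object of class `hand_skeleton`: list with `bones` (data.frame
#'   `name`, `parent`, `length_mm`), `handedness`, `scale`.
#' @examples
#' sk <- default_skeleton()
#' nrow(sk$bones)           # 22
#' joints_of(sk)$name[1:3]  # elbow, wrist, thumb CMC
#' @export
default_skeleton <- function(handedness = c("right", "left"), scale = 1) {
  handedness <- match.arg(handedness)
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale), scale > 0)
  bones <- hand_bone_table()
  bones$length_mm <- unname(DEFAULT_LENGTHS_MM[bones$name]) * scale
  structure(list(bones = bones, handedness = handedness, scale = scale),
            class = "hand_skeleton")
}

validate_skeleton <- function(skeleton) {
  if (!inherits(skeleton, "hand_skeleton"))
    stop("not a hand_skeleton object", call. = FALSE)
  b <- skeleton$bones
  if (anyDuplicated(b$name)) stop("duplicate bone names", call. = FALSE)
  root <- b$name[is.na(b$parent)]
  if (!identical(root, "forearm"))
    stop("skeleton must be rooted at the forearm", call. = FALSE)
  if (!all(b$parent[!is.na(b$parent)] %in% b$name))
    stop("unknown parent bone", call. = FALSE)
  lens <- b$length_mm
  zero_ok <- b$name == digit_bone(1, "metacarpal")
  if (any(lens < 0) || any(lens[!zero_ok] <= 0))
    stop("segment lengths must be > 0 (thumb metacarpal may be 0)",
         call. = FALSE)
  invisible(skeleton)
}

#' @export
print.hand_skeleton <- function(x, ...) {
  cat(sprintf("hand_skeleton: %d bones, %s hand, scale %g\n",
              nrow(x$bones), x$handedness, x$scale))
  invisible(x)
}

#' Ordered joint definitions of a skeleton
#'
#' Returns the joint table in the canonical order: elbow (forearm against the
#' fixed upper-arm/global frame), wrist (hand vs forearm), then digits 1..5
#' proximal-to-distal (CMC, MCP, PIP, DIP per digit; the thumb's
#' interphalangeal joint is aliased IP).  `dof` holds the enabled degrees of
#' freedom per joint as a comma-separated subset of
#' `flexion`,`abduction`,`rotation`; only these are exported to driver files,
#' but angle extraction always computes all three.
#'
#' DOF policy: elbow = flexion + rotation (pronation/supination); wrist =
#' flexion + abduction; thumb CMC = all three; finger MCPs = flexion +
#' abduction; PIP/DIP and thumb MCP/IP = flexion; non-thumb CMC joints are
#' rigid (empty mask) since the palm is treated as one unit.
#'
#' @param skeleton a `hand_skeleton`.
#' @return data.frame with columns `name`, `child_bone`, `parent_bone`
#'   (`NA` for the elbow: its parent frame is the fixed global frame),
#'   `digit` (0 for elbow/wrist), `dof`.
#' @export
joints_of <- function(skeleton) {
  validate_skeleton(skeleton)
  rows <- list(
    data.frame(name = "elbow", child_bone = "forearm",
               parent_bone = NA_character_, digit = 0L,
               dof = "flexion,rotation"),
    data.frame(name = "wrist", child_bone = "hand",
               parent_bone = "forearm", digit = 0L,
               dof = "flexion,abduction")
  )
  for (d in 1:5) {
    segs <- digit_bone(d, SEGMENT_NAMES)
    jn <- if (d == 1) c("cmc", "mcp", "ip", "dp") else c("cmc", "mcp", "pip", "dip")
    dof <- if (d == 1) {
      # thumb: CMC carries opposition (3 DOF); the extra distal joint of the
      # uniform 4-bone chain is left rigid (no intermediate phalanx in vivo)
      c("flexion,abduction,rotation", "flexion", "flexion", "")
    } else {
      c("", "flexion,abduction", "flexion", "flexion")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("finger%d_%s", d, jn),
      child_bone = segs,
      parent_bone = c("hand", segs[1:3]),
      digit = d, dof = dof)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

joint_dofs <- function(dof_string) {
  if (!nzchar(dof_string)) character(0) else strsplit(dof_string, ",")[[1]]
}

#' Neutral-zero reference posture of a skeleton
#'
#' The flat outstretched hand: every bone basis is the identity matrix and
#' positions chain distally along the global Z axis (`offset = (0, 0,
#' length)` in the parent frame).  All relative joint rotations are the
#' identity, so every joint angle measured against this posture is zero.
#'
#' @param skeleton a `hand_skeleton`.
#' @return list with `bases` (named list of 3x3 identity matrices, one per
#'   bone) and `positions` (named list of proximal-end positions, mm) and
#'   `tips` (fingertip positions per digit).
#' @export
reference_posture <- function(skeleton) {
  validate_skeleton(skeleton)
  b <- skeleton$bones
  bases <- stats::setNames(rep(list(diag(3)), nrow(b)), b$name)
  pos <- stats::setNames(rep(list(c(0, 0, 0)), nrow(b)), b$name)
  for (i in seq_len(nrow(b))) {
    p <- b$parent[i]
    if (!is.na(p))
      pos[[b$name[i]]] <- pos[[p]] + c(0, 0, b$length_mm[b$name == p])
  }
  tips <- lapply(1:5, function(d) {
    dp <- digit_bone(d, "distal")
    pos[[dp]] + c(0, 0, b$length_mm[b$name == dp])
  })
  names(tips) <- as.character(1:5)
  list(bases = bases, positions = pos, tips = tips)
}

#' Write / read a skeleton definition file
#'
#' Plain-text key/value grammar, one bone per line:
#' ```
#' # comment lines allowed
#' handedness right
#' scale 1
#' bone <name> <parent|-> <length_mm>
#' ```
#' Lengths are serialized with 17 significant digits so the round trip is
#' lossless.
#'
#' @param skeleton a `hand_skeleton`.
#' @param path file path.
#' @return `read_skeleton` returns a `hand_skeleton`; `write_skeleton`
#'   returns `path` invisibly.
#' @export
write_skeleton <- function(skeleton, path) {
  validate_skeleton(skeleton)
  b <- skeleton$bones
  lines <- c(
    "# handmotion skeleton v1",
    paste("handedness", skeleton$handedness),
    paste("scale", sprintf("%.17g", skeleton$scale)),
    sprintf("bone %s %s %.17g", b$name,
            ifelse(is.na(b$parent), "-", b$parent), b$length_mm))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_skeleton
#' @export
read_skeleton <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  handedness <- "right"; scale <- 1
  name <- character(0); parent <- character(0); len <- numeric(0)
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    switch(tok[1],
      handedness = { handedness <- tok[2] },
      scale = { scale <- as.numeric(tok[2]) },
      bone = {
        if (length(tok) != 4L)
          stop("malformed bone line: ", ln, call. = FALSE)
        name <- c(name, tok[2])
        parent <- c(parent, if (tok[3] == "-") NA_character_ else tok[3])
        len <- c(len, as.numeric(tok[4]))
      },
      stop("unknown directive in skeleton file: ", tok[1], call. = FALSE))
  }
  sk <- structure(
    list(bones = data.frame(name = name, parent = parent, length_mm = len,
                            stringsAsFactors = FALSE),
         handedness = handedness, scale = scale),
    class = "hand_skeleton")
  validate_skeleton(sk)
  sk
}
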