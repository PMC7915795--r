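# Joint-driver vector files for the downstream musculoskeletal simulation:
# per body part (Finger1..Finger5, Wrist, Elbow) one file of named angle
# vectors, a normalized time-series vector, and the finger-length scaling
# file.
#
# File grammar (one assignment per vector, angles in DEGREES, 6 decimals):
#   // comment
#   Finger2.Joint_MC_PP.Flexion = {0.000000, 1.234567, ...};
# The name scheme is <Part>.Joint_<PARENT>_<CHILD>.<Dof> with bone
# abbreviations Carpus/MC/PP/IP/DP (Forearm/Global for wrist and elbow).
# Compatibility with any particular simulation product's syntax is not
# claimed; a reader for the same grammar ships for testing.

DOF_LABELS <- c(flexion = "Flexion", abduction = "Abduction",
                rotation = "Rotation")
DOF_AXIS <- c(flexion = "phi", abduction = "theta", rotation = "psi")

bone_abbrev <- function(bone) {
  if (bone == "forearm") return("Forearm")
  if (bone == "hand") return("Carpus")
  seg <- sub("^finger[0-9]+_", "", bone)
  unname(SEGMENT_ABBREV[seg])
}

driver_part <- function(joint_row) {
  if (joint_row$name == "elbow") "Elbow"
  else if (joint_row$name == "wrist") "Wrist"
  else sprintf("Finger%d", joint_row$digit)
}

driver_vector_name <- function(joint_row, dof) {
  parent <- if (is.na(joint_row$parent_bone)) "Global"
            else bone_abbrev(joint_row$parent_bone)
  sprintf("%s.Joint_%s_%s.%s", driver_part(joint_row), parent,
          bone_abbrev(joint_row$child_bone), DOF_LABELS[[dof]])
}

#' Evenly spaced normalized time-series vector
#'
#' The interpolation abscissa for the joint drivers: `n_frames` evenly
#' spaced numbers from 0 to 1 inclusive.
#'
#' @param n_frames number of recorded frames (>= 2).
#' @return Numeric vector `c(0, 1/(n-1), ..., 1)`.
#' @export
make_time_series <- function(n_frames) {
  if (!(is.numeric(n_frames) && length(n_frames) == 1L && n_frames >= 2))
    stop("n_frames must be >= 2", call. = FALSE)
  seq(0, 1, length.out = as.integer(n_frames))
}

#' Export joint-driver vector files
#'
#' Writes one file per body part — `Finger1.any` .. `Finger5.any`,
#' `Wrist.any`, `Elbow.any` — containing, per joint, one named angle vector
#' (degrees) per enabled degree of freedom, plus `TimeSeries.any` with the
#' normalized abscissa.  Vectors for disabled DOFs are suppressed.  When
#' `finger_lengths` is supplied, `FingerLength.any` is written as well.
#'
#' @param series an `angle_set`.
#' @param dir destination directory (created if absent).
#' @param finger_lengths optional result of [compute_finger_lengths()].
#' @param provenance optional provenance comment written into each file.
#' @return Invisibly, a named list: per written file the named list of
#'   vectors it contains.
#' @export
export_driver_files <- function(series, dir, finger_lengths = NULL,
                                provenance = NULL) {
  if (!inherits(series, "angle_set")) stop("expected an angle_set", call. = FALSE)
  nfr <- vapply(series$angles, nrow, integer(1))
  if (length(nfr) == 0L) stop("empty angle series", call. = FALSE)
  if (length(unique(nfr)) != 1L)
    stop("frame count mismatch across joint series", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  joints <- series$joints
  parts <- c(sprintf("Finger%d", 1:5), "Wrist", "Elbow")
  written <- list()
  for (part in parts) {
    vectors <- list()
    for (j in seq_len(nrow(joints))) {
      jr <- joints[j, ]
      if (driver_part(jr) != part) next
      for (dof in joint_dofs(jr$dof)) {
        vectors[[driver_vector_name(jr, dof)]] <-
          series$angles[[jr$name]][, DOF_AXIS[[dof]]]
      }
    }
    path <- file.path(dir, paste0(part, ".any"))
    write_driver_file(vectors, path, provenance)
    written[[paste0(part, ".any")]] <- vectors
  }
  ts <- list(Main.TimeSeries = make_time_series(series$frame_count))
  write_driver_file(ts, file.path(dir, "TimeSeries.any"), provenance)
  written[["TimeSeries.any"]] <- ts
  if (!is.null(finger_lengths)) {
    fl <- finger_length_vectors(finger_lengths)
    write_driver_file(fl, file.path(dir, "FingerLength.any"), provenance)
    written[["FingerLength.any"]] <- fl
  }
  invisible(written)
}

finger_length_vectors <- function(finger_lengths) {
  v <- stats::setNames(as.list(finger_lengths$length_mm),
                       sprintf("Finger%d.Length_%s", finger_lengths$digit,
                               SEGMENT_ABBREV[finger_lengths$segment]))
  lapply(v, as.numeric)
}

#' Write / read a driver vector file
#'
#' The minimal declarative grammar used by all exported files: `Name = {v1,
#' v2, ...};`, `//` comments, values printed with 6 decimals.
#'
#' @param vectors named list of numeric vectors.
#' @param path file path.
#' @param provenance optional provenance comment.
#' @return `read_driver_file` returns a named list of numeric vectors;
#'   `write_driver_file` returns `path` invisibly.
#' @export
write_driver_file <- function(vectors, path, provenance = NULL) {
  lines <- c("// handmotion driver file v1 — angles in degrees, lengths in mm",
             if (!is.null(provenance)) paste("//", provenance))
  for (nm in names(vectors)) {
    lines <- c(lines, sprintf("%s = {%s};", nm,
                              paste(sprintf("%.6f", vectors[[nm]]),
                                    collapse = ", ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_driver_file
#' @export
read_driver_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "//")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*\\{(.*)\\};$", ln))[[1]]
    if (length(m) != 3L)
      stop("malformed driver line: ", ln, call. = FALSE)
    vals <- as.numeric(strsplit(m[3], ",")[[1]])
    if (anyNA(vals)) stop("non-numeric value in vector ", m[2], call. = FALSE)
    out[[m[2]]] <- vals
  }
  out
}

#' Extract finger segment lengths from a recording
#'
#' Per digit and per bone, the Euclidean distance between the bone's
#' proximal and distal joint positions: the next bone's proximal position,
#' or the recorded fingertip for the distal phalanx.  By default lengths are
#' measured at frame 0 (the sensor's model keeps them constant); the
#' `"mean"` estimator averages over all frames, which suppresses position
#' noise.
#'
#' @param recording a `hand_recording`.
#' @param estimator `"frame0"` (default) or `"mean"`.
#' @return data.frame with columns `digit`, `segment`, `bone`, `length_mm`.
#' @export
compute_finger_lengths <- function(recording,
                                   estimator = c("frame0", "mean")) {
  estimator <- match.arg(estimator)
  if (!inherits(recording, "hand_recording"))
    stop("expected a hand_recording", call. = FALSE)
  frames <- if (estimator == "frame0") recording$frames[1] else recording$frames
  rows <- list()
  for (d in 1:5) {
    for (s in seq_along(SEGMENT_NAMES)) {
      bn <- digit_bone(d, SEGMENT_NAMES[s])
      lens <- vapply(frames, function(f) {
        p0 <- f$positions[[bn]]
        p1 <- if (s < 4L) f$positions[[digit_bone(d, SEGMENT_NAMES[s + 1])]]
              else f$tips[[as.character(d)]]
        if (is.null(p0) || is.null(p1))
          stop("missing positions for ", bn, call. = FALSE)
        sqrt(sum((p1 - p0)^2))
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        digit = d, segment = SEGMENT_NAMES[s], bone = bn,
        length_mm = mean(lens), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
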