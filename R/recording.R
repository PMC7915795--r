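# The Recording container and its plain-text serialization.
#
# A recording is what the sensor (or the synthetic generator) produces: per
# frame, one state per bone — proximal-end position (mm, global frame) and
# the 3x3 orientation basis (rows = local axes in global coordinates) — plus
# the five fingertip positions, which the driver-export module needs for
# finger-length extraction.

#' Construct a recording
#'
#' Assembles and validates a recording object.  Frame 0 is treated as the
#' reference (neutral-zero) posture t0 by downstream angle extraction unless
#' an explicit reference is supplied there.
#'
#' @param skeleton a `hand_skeleton`.
#' @param frames list of frames; each frame is a list with `time_s`
#'   (seconds), `positions` (named list of length-3 vectors, one per bone),
#'   `bases` (named list of 3x3 rotation matrices, one per bone), `tips`
#'   (named list `"1"`..`"5"` of fingertip positions).
#' @param frame_rate frames per second (> 0).
#' @param provenance optional character string recorded in the file header
#'   (seed, generator settings).
#' @return Object of class `hand_recording`.
#' @export
new_recording <- function(skeleton, frames, frame_rate, provenance = NULL) {
  validate_skeleton(skeleton)
  stopifnot(is.numeric(frame_rate), length(frame_rate) == 1L, frame_rate > 0)
  if (length(frames) < 2L)
    stop("a recording needs at least 2 frames", call. = FALSE)
  bone_names <- skeleton$bones$name
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    missing <- setdiff(bone_names, names(f$bases))
    if (length(missing) > 0L)
      stop(sprintf("incomplete frame %d: missing bone state for %s",
                   i - 1L, paste(missing, collapse = ", ")), call. = FALSE)
  }
  t <- vapply(frames, function(f) f$time_s, numeric(1))
  if (any(diff(t) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  structure(list(skeleton = skeleton, frames = frames,
                 frame_rate = frame_rate, provenance = provenance),
            class = "hand_recording")
}

#' @export
print.hand_recording <- function(x, ...) {
  cat(sprintf("hand_recording: %d frames at %g Hz, %d bones (%s hand)\n",
              length(x$frames), x$frame_rate, nrow(x$skeleton$bones),
              x$skeleton$handedness))
  invisible(x)
}

n_frames <- function(recording) length(recording$frames)

fmt_nums <- function(x) paste(sprintf("%.17g", x), collapse = " ")

#' Write / read the plain-text recording format
#'
#' One frame per block.  Grammar (whitespace separated; `#` starts a
#' comment):
#' ```
#' # provenance line(s)
#' frame_rate <hz>
#' handedness <left|right>
#' scale <s>
#' bone <name> <parent|-> <length_mm>        (one per bone; defines skeleton)
#' frames <n>
#' frame <index> <time_s>
#' <bone-name> <px py pz> <b11 b12 b13 b21 b22 b23 b31 b32 b33>
#' tip <digit> <x y z>                       (five per frame)
#' ```
#' Numbers use 17 significant digits; the round trip is lossless at double
#' precision.  Bases are ingested through [orthonormalize()] with the 1e-3
#' tolerance on read.
#'
#' @param recording a `hand_recording`.
#' @param path file path.
#' @return `read_recording` returns a `hand_recording`; `write_recording`
#'   returns `path` invisibly.
#' @export
write_recording <- function(recording, path) {
  sk <- recording$skeleton
  b <- sk$bones
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    "# handmotion recording v1",
    if (!is.null(recording$provenance)) paste("#", recording$provenance),
    sprintf("frame_rate %.17g", recording$frame_rate),
    paste("handedness", sk$handedness),
    sprintf("scale %.17g", sk$scale),
    sprintf("bone %s %s %.17g", b$name,
            ifelse(is.na(b$parent), "-", b$parent), b$length_mm),
    sprintf("frames %d", length(recording$frames)))
  writeLines(hdr, con)
  for (i in seq_along(recording$frames)) {
    f <- recording$frames[[i]]
    writeLines(sprintf("frame %d %.17g", i - 1L, f$time_s), con)
    for (bn in b$name) {
      writeLines(paste(bn, fmt_nums(f$positions[[bn]]),
                       fmt_nums(as.vector(t(f$bases[[bn]])))), con)
    }
    for (d in 1:5)
      writeLines(paste("tip", d, fmt_nums(f$tips[[as.character(d)]])), con)
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path))
    stop("cannot read recording file: ", path, call. = FALSE)
  raw <- readLines(path)
  lines <- trimws(raw)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  i <- 1L
  nxt <- function() {
    if (i > length(lines)) stop("unexpected end of recording file", call. = FALSE)
    tok <- strsplit(lines[i], "[[:space:]]+")[[1]]
    i <<- i + 1L
    tok
  }
  bad <- function(msg) stop(sprintf("recording parse error at line %d: %s",
                                    lineno[i - 1L], msg), call. = FALSE)
  frame_rate <- NA_real_; handedness <- "right"; scale <- 1
  name <- character(0); parent <- character(0); len <- numeric(0)
  nframes <- NA_integer_
  repeat {
    tok <- nxt()
    if (tok[1] == "frame_rate") frame_rate <- as.numeric(tok[2])
    else if (tok[1] == "handedness") handedness <- tok[2]
    else if (tok[1] == "scale") scale <- as.numeric(tok[2])
    else if (tok[1] == "bone") {
      if (length(tok) != 4L) bad("malformed bone line")
      name <- c(name, tok[2])
      parent <- c(parent, if (tok[3] == "-") NA_character_ else tok[3])
      len <- c(len, as.numeric(tok[4]))
    } else if (tok[1] == "frames") {
      nframes <- as.integer(tok[2]); break
    } else bad(paste("unknown header directive", tok[1]))
  }
  sk <- structure(
    list(bones = data.frame(name = name, parent = parent, length_mm = len,
                            stringsAsFactors = FALSE),
         handedness = handedness, scale = scale),
    class = "hand_skeleton")
  validate_skeleton(sk)
  frames <- vector("list", nframes)
  for (k in seq_len(nframes)) {
    tok <- nxt()
    if (tok[1] != "frame") bad("expected a frame line")
    time_s <- as.numeric(tok[3])
    positions <- list(); bases <- list(); tips <- list()
    for (bn in seq_along(name)) {
      tok <- nxt()
      if (length(tok) != 13L) bad("expected bone state: name + 3 + 9 numbers")
      if (!(tok[1] %in% name)) bad(paste("unknown bone", tok[1]))
      v <- as.numeric(tok[-1])
      if (anyNA(v)) bad("non-numeric bone state")
      positions[[tok[1]]] <- v[1:3]
      bases[[tok[1]]] <- orthonormalize(matrix(v[4:12], 3, 3, byrow = TRUE))
    }
    for (d in 1:5) {
      tok <- nxt()
      if (tok[1] != "tip") bad("expected a tip line")
      tips[[tok[2]]] <- as.numeric(tok[3:5])
    }
    frames[[k]] <- list(time_s = time_s, positions = positions,
                        bases = bases, tips = tips)
  }
  new_recording(sk, frames, frame_rate)
}
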