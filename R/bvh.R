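# Biovision Hierarchy (BVH) reading, writing and frame slicing.
#
# Dialect: the root (forearm) carries 6 channels "Xposition Yposition
# Zposition Zrotation Xrotation Yrotation"; every other joint carries
# "Zrotation Xrotation Yrotation" — the dominant channel order among BVH
# tools.  The mapping between channels and Cardan angles is fixed:
# Xrotation <- phi, Yrotation <- theta, Zrotation <- psi.  Offsets are in
# mm, rotations in degrees, all numerics printed with 6 decimals.  Frame
# indexing is 0-based and slices are half-open [start, end).

ROT_CHANNELS <- c("Zrotation", "Xrotation", "Yrotation")

#' Build a BVH document from a skeleton and joint-angle series
#'
#' The hierarchy mirrors the bone tree rooted at the forearm; each node's
#' rotation channels carry the Cardan triple of the joint that drives the
#' node's bone (the root's rotations are the elbow angles).  `End Site`
#' blocks close each digit with the distal-phalanx offset.
#'
#' @param skeleton a `hand_skeleton`.
#' @param series an `angle_set` covering the skeleton's joints.
#' @param frame_rate frames per second; `Frame Time` is its reciprocal.
#' @param path optional file path; when given the document is also written.
#' @return Object of class `bvh_document`: list with `nodes` (data.frame
#'   `name`, `parent`, `offset_x/y/z`, `channels` as a single
#'   space-separated string, `end_site_x/y/z` or NA), `motion` (frame x
#'   channel matrix), `frame_time_s`.
#' @export
write_bvh <- function(skeleton, series, frame_rate = series$frame_rate,
                      path = NULL) {
  validate_skeleton(skeleton)
  if (!inherits(series, "angle_set")) stop("expected an angle_set", call. = FALSE)
  if (length(series$angles) == 0L || series$frame_count < 1L)
    stop("empty angle series", call. = FALSE)
  nfr <- vapply(series$angles, nrow, integer(1))
  if (length(unique(nfr)) != 1L)
    stop("frame count mismatch across joint series", call. = FALSE)
  joints <- series$joints
  b <- skeleton$bones
  joint_of_bone <- stats::setNames(joints$name, joints$child_bone)

  plen <- function(bn) {
    p <- b$parent[b$name == bn]
    if (is.na(p)) 0 else b$length_mm[b$name == p]
  }
  nodes <- data.frame(
    name = b$name, parent = b$parent,
    offset_x = 0, offset_y = 0,
    offset_z = vapply(b$name, plen, numeric(1)),
    channels = ifelse(is.na(b$parent),
                      paste(c("Xposition", "Yposition", "Zposition",
                              ROT_CHANNELS), collapse = " "),
                      paste(ROT_CHANNELS, collapse = " ")),
    end_site_x = NA_real_, end_site_y = NA_real_, end_site_z = NA_real_,
    stringsAsFactors = FALSE)
  is_leaf <- !(b$name %in% b$parent)
  nodes$end_site_x[is_leaf] <- 0
  nodes$end_site_y[is_leaf] <- 0
  nodes$end_site_z[is_leaf] <- b$length_mm[is_leaf]

  nf <- series$frame_count
  cols <- list()
  for (k in seq_len(nrow(nodes))) {
    ang <- series$angles[[joint_of_bone[[nodes$name[k]]]]]
    if (is.null(ang))
      stop("series missing joint for bone ", nodes$name[k], call. = FALSE)
    if (is.na(nodes$parent[k]))
      cols[[length(cols) + 1L]] <- matrix(0, nf, 3) # root position channels
    # channel order Z X Y <- psi phi theta
    cols[[length(cols) + 1L]] <- ang[, c("psi", "phi", "theta"), drop = FALSE]
  }
  motion <- do.call(cbind, cols)
  dimnames(motion) <- NULL
  doc <- structure(list(nodes = nodes, motion = motion,
                        frame_time_s = 1 / frame_rate),
                   class = "bvh_document")
  if (!is.null(path)) writeLines(bvh_text(doc), path)
  doc
}

#' @export
print.bvh_document <- function(x, ...) {
  cat(sprintf("bvh_document: %d joints, %d frames, frame time %.6f s\n",
              nrow(x$nodes), nrow(x$motion), x$frame_time_s))
  invisible(x)
}

fmt6 <- function(x) sprintf("%.6f", x)

#' Serialize a BVH document to text
#'
#' @param doc a `bvh_document`.
#' @return Character vector of lines (HIERARCHY then MOTION).
#' @export
bvh_text <- function(doc) {
  nodes <- doc$nodes
  out <- character(0)
  emit <- function(s) out[[length(out) + 1L]] <<- s
  recurse <- function(name, depth) {
    ind <- strrep("  ", depth)
    k <- which(nodes$name == name)
    kw <- if (is.na(nodes$parent[k])) "ROOT" else "JOINT"
    emit(paste0(ind, kw, " ", name))
    emit(paste0(ind, "{"))
    ind2 <- strrep("  ", depth + 1)
    emit(paste0(ind2, "OFFSET ", fmt6(nodes$offset_x[k]), " ",
                fmt6(nodes$offset_y[k]), " ", fmt6(nodes$offset_z[k])))
    ch <- strsplit(nodes$channels[k], " ")[[1]]
    emit(paste0(ind2, "CHANNELS ", length(ch), " ",
                paste(ch, collapse = " ")))
    children <- nodes$name[!is.na(nodes$parent) & nodes$parent == name]
    for (cn in children) recurse(cn, depth + 1)
    if (!is.na(nodes$end_site_x[k])) {
      emit(paste0(ind2, "End Site"))
      emit(paste0(ind2, "{"))
      emit(paste0(strrep("  ", depth + 2), "OFFSET ",
                  fmt6(nodes$end_site_x[k]), " ", fmt6(nodes$end_site_y[k]),
                  " ", fmt6(nodes$end_site_z[k])))
      emit(paste0(ind2, "}"))
    }
    emit(paste0(ind, "}"))
  }
  emit("HIERARCHY")
  recurse(nodes$name[is.na(nodes$parent)], 0)
  emit("MOTION")
  emit(sprintf("Frames: %d", nrow(doc$motion)))
  emit(sprintf("Frame Time: %.6f", doc$frame_time_s))
  for (i in seq_len(nrow(doc$motion)))
    emit(paste(fmt6(doc$motion[i, ]), collapse = " "))
  out
}

#' Write a BVH document object to a file
#'
#' @param doc a `bvh_document`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_bvh_document <- function(doc, path) {
  writeLines(bvh_text(doc), path)
  invisible(path)
}

#' Read a BVH file
#'
#' Parses the HIERARCHY and MOTION sections.  When the joint names match
#' this package's hand-skeleton naming the motion is additionally re-mapped
#' into per-joint Cardan series (`angles`); otherwise the document is
#' returned as a generic hierarchy with `angles = NULL` and no silent
#' renaming.
#'
#' @param path file path of a BVH text file.
#' @return List with `doc` (a `bvh_document`), `frame_rate`, and `angles`
#'   (an `angle_set` or `NULL`), plus `skeleton` (a `hand_skeleton` rebuilt
#'   from the offsets, or `NULL` for non-conforming hierarchies).
#' @export
read_bvh <- function(path) {
  if (!file.exists(path))
    stop("cannot read BVH file: ", path, call. = FALSE)
  lines <- readLines(path)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  i <- 0L
  nxt <- function() {
    repeat {
      i <<- i + 1L
      if (i > length(lines))
        stop("BVH parse error: unexpected end of file after line ",
             length(lines), call. = FALSE)
      if (length(toks[[i]]) > 0L && nzchar(toks[[i]][1])) return(toks[[i]])
    }
  }
  bad <- function(msg) stop(sprintf("BVH parse error at line %d: %s", i, msg),
                            call. = FALSE)
  tok <- nxt()
  if (tok[1] != "HIERARCHY") bad("expected HIERARCHY")
  nodes <- data.frame(name = character(0), parent = character(0),
                      offset_x = numeric(0), offset_y = numeric(0),
                      offset_z = numeric(0), channels = character(0),
                      end_site_x = numeric(0), end_site_y = numeric(0),
                      end_site_z = numeric(0), stringsAsFactors = FALSE)
  parse_node <- function(kw_tok, parent) {
    name <- kw_tok[2]
    if (is.na(name)) bad("joint without a name")
    if (nxt()[1] != "{") bad("expected {")
    off <- nxt()
    if (off[1] != "OFFSET" || length(off) != 4L) bad("expected OFFSET x y z")
    ch <- nxt()
    if (ch[1] != "CHANNELS") bad("expected CHANNELS")
    nch <- as.integer(ch[2])
    if (is.na(nch) || length(ch) != 2L + nch) bad("channel count mismatch")
    row <- data.frame(name = name, parent = parent,
                      offset_x = as.numeric(off[2]),
                      offset_y = as.numeric(off[3]),
                      offset_z = as.numeric(off[4]),
                      channels = paste(ch[-(1:2)], collapse = " "),
                      end_site_x = NA_real_, end_site_y = NA_real_,
                      end_site_z = NA_real_, stringsAsFactors = FALSE)
    nodes <<- rbind(nodes, row)
    my <- nrow(nodes)
    repeat {
      tok <- nxt()
      if (tok[1] == "JOINT") parse_node(tok, name)
      else if (tok[1] == "End" && length(tok) >= 2 && tok[2] == "Site") {
        if (nxt()[1] != "{") bad("expected { after End Site")
        eo <- nxt()
        if (eo[1] != "OFFSET") bad("expected OFFSET in End Site")
        nodes$end_site_x[my] <<- as.numeric(eo[2])
        nodes$end_site_y[my] <<- as.numeric(eo[3])
        nodes$end_site_z[my] <<- as.numeric(eo[4])
        if (nxt()[1] != "}") bad("expected } after End Site")
      } else if (tok[1] == "}") break
      else bad(paste("unexpected token", tok[1]))
    }
  }
  tok <- nxt()
  if (tok[1] != "ROOT") bad("expected ROOT")
  parse_node(tok, NA_character_)
  tok <- nxt()
  if (tok[1] != "MOTION") bad("expected MOTION")
  tok <- nxt()
  if (tok[1] != "Frames:") bad("expected Frames:")
  nf <- as.integer(tok[2])
  tok <- nxt()
  if (!(tok[1] == "Frame" && tok[2] == "Time:")) bad("expected Frame Time:")
  frame_time <- as.numeric(tok[3])
  if (!is.finite(frame_time) || frame_time <= 0) bad("invalid frame time")
  nchan <- sum(lengths(strsplit(nodes$channels, " ")))
  motion <- matrix(NA_real_, nf, nchan)
  for (r in seq_len(nf)) {
    tok <- nxt()
    v <- suppressWarnings(as.numeric(tok))
    if (length(v) != nchan || anyNA(v))
      bad(sprintf("motion row %d: expected %d numeric channels, got %d",
                  r - 1L, nchan, length(tok)))
    motion[r, ] <- v
  }
  doc <- structure(list(nodes = nodes, motion = motion,
                        frame_time_s = frame_time), class = "bvh_document")
  res <- list(doc = doc, frame_rate = 1 / frame_time, angles = NULL,
              skeleton = NULL)
  mapped <- try(bvh_to_angles(doc), silent = TRUE)
  if (!inherits(mapped, "try-error")) {
    res$angles <- mapped$angles
    res$skeleton <- mapped$skeleton
  }
  res
}

# Re-map a conforming BVH document back into skeleton + angle_set.  Errors
# when the hierarchy does not match the package's hand-skeleton naming.
bvh_to_angles <- function(doc) {
  nodes <- doc$nodes
  expect <- hand_bone_table()
  if (!identical(sort(nodes$name), sort(expect$name)))
    stop("non-conforming BVH joint names", call. = FALSE)
  # segment length of a bone = child's offset (or its End Site offset)
  lens <- vapply(nodes$name, function(bn) {
    ch <- which(!is.na(nodes$parent) & nodes$parent == bn)
    if (length(ch) > 0L)
      sqrt(sum(unlist(nodes[ch[1], c("offset_x", "offset_y", "offset_z")])^2))
    else {
      k <- which(nodes$name == bn)
      sqrt(sum(unlist(nodes[k, c("end_site_x", "end_site_y", "end_site_z")])^2))
    }
  }, numeric(1))
  sk <- structure(
    list(bones = data.frame(name = nodes$name, parent = nodes$parent,
                            length_mm = unname(lens), stringsAsFactors = FALSE),
         handedness = "right", scale = 1),
    class = "hand_skeleton")
  validate_skeleton(sk)
  joints <- joints_of(sk)
  joint_of_bone <- stats::setNames(joints$name, joints$child_bone)
  # channel column ranges per node, in document order
  nch <- lengths(strsplit(nodes$channels, " "))
  ends <- cumsum(nch)
  starts <- ends - nch + 1L
  angles <- stats::setNames(vector("list", nrow(joints)), joints$name)
  nf <- nrow(doc$motion)
  for (k in seq_len(nrow(nodes))) {
    ch <- strsplit(nodes$channels[k], " ")[[1]]
    cols <- seq(starts[k], ends[k])
    m <- matrix(0, nf, 3, dimnames = list(NULL, c("phi", "theta", "psi")))
    m[, "phi"] <- doc$motion[, cols[ch == "Xrotation"]]
    m[, "theta"] <- doc$motion[, cols[ch == "Yrotation"]]
    m[, "psi"] <- doc$motion[, cols[ch == "Zrotation"]]
    angles[[joint_of_bone[[nodes$name[k]]]]] <- m
  }
  list(skeleton = sk,
       angles = new_angle_set(joints, angles, 1 / doc$frame_time_s))
}

#' Slice a range of frames from a BVH document
#'
#' Keeps motion rows `[start, end)` (0-based, half-open); the hierarchy is
#' unchanged and the frame count updated.
#'
#' @param doc a `bvh_document`.
#' @param start first frame to keep (0-based).
#' @param end one past the last frame to keep; `start < end <= frame_count`.
#' @return A `bvh_document` with `end - start` frames.
#' @export
slice_frames <- function(doc, start, end) {
  nf <- nrow(doc$motion)
  if (!(start >= 0 && start < end && end <= nf))
    stop(sprintf("invalid slice [%d, %d) for %d frames", start, end, nf),
         call. = FALSE)
  doc$motion <- doc$motion[(start + 1L):end, , drop = FALSE]
  doc
}
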