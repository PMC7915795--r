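# Validation against 2D marker tracking: the accuracy-measurement method.
# A video camera films the index finger side-on while the sensor records;
# the PIP flexion angle computed from three tracked markers (MCP, PIP,
# fingertip) is compared with the basis-derived Cardan angle.  Here the
# camera is replaced by an orthographic projection of the synthetic
# recording.

#' Flexion angle from three tracked 2D marker positions
#'
#' The angle between the proximal segment (MCP -> PIP) and the distal
#' segment (PIP -> fingertip), in degrees within [0, 180): 0 = straight
#' finger, growing with flexion.  Invariant under rigid 2D rotation,
#' translation and uniform scaling of the three points.
#'
#' @param p_mcp,p_pip,p_tip length-2 numeric vectors (x, y), arbitrary
#'   planar units.
#' @return Angle in degrees.
#' @export
angle_from_markers <- function(p_mcp, p_pip, p_tip) {
  v1 <- p_pip - p_mcp
  v2 <- p_tip - p_pip
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 <= 0 || n2 <= 0 || !is.finite(n1) || !is.finite(n2))
    stop("degenerate markers: coincident points", call. = FALSE)
  cross <- v1[1] * v2[2] - v1[2] * v2[1]
  dot <- sum(v1 * v2)
  ang <- atan2(abs(cross), dot) * RAD2DEG
  if (ang >= 180) 0 else ang
}

#' Project a recording's finger markers into a 2D camera view
#'
#' Synthetic stand-in for the validation camera: orthographically projects
#' the digit's MCP joint, PIP joint and fingertip positions onto the view
#' plane.  `"side"` looks along the flexion (X) axis at the sagittal plane
#' of the finger — image coordinates are (z, -y) so flexion sweeps the
#' finger downward as in the physical setup.  `"top"` looks along the palm
#' normal (Y) — image coordinates are (z, x).
#'
#' @param recording a `hand_recording`.
#' @param digit digit number (default 2, the index finger used in the
#'   experiment).
#' @param view `"side"` or `"top"`.
#' @return Object of class `marker_track`: list with `frame_rate` and
#'   `markers`, an n x 6 matrix with columns `x_mcp`, `y_mcp`, `x_pip`,
#'   `y_pip`, `x_tip`, `y_tip`.
#' @export
project_recording <- function(recording, digit = 2, view = c("side", "top")) {
  view <- match.arg(view)
  if (!inherits(recording, "hand_recording"))
    stop("expected a hand_recording", call. = FALSE)
  proj <- if (view == "side") function(p) c(p[3], -p[2])
          else function(p) c(p[3], p[1])
  mcp_bone <- digit_bone(digit, "proximal")      # MCP joint = PP proximal end
  pip_bone <- digit_bone(digit, "intermediate")  # PIP joint = IP proximal end
  m <- t(vapply(recording$frames, function(f) {
    c(proj(f$positions[[mcp_bone]]), proj(f$positions[[pip_bone]]),
      proj(f$tips[[as.character(digit)]]))
  }, numeric(6)))
  colnames(m) <- c("x_mcp", "y_mcp", "x_pip", "y_pip", "x_tip", "y_tip")
  structure(list(markers = m, frame_rate = recording$frame_rate),
            class = "marker_track")
}

#' Per-frame marker angles of a 2D track
#'
#' Applies [angle_from_markers()] to every frame of a track.
#'
#' @param track a `marker_track`.
#' @return Numeric vector of angles in degrees, one per frame.
#' @export
marker_angle_series <- function(track) {
  m <- track$markers
  vapply(seq_len(nrow(m)), function(i) {
    angle_from_markers(m[i, c("x_mcp", "y_mcp")], m[i, c("x_pip", "y_pip")],
                       m[i, c("x_tip", "y_tip")])
  }, numeric(1))
}

#' Write / read a 2D marker track as CSV
#'
#' Column layout `frame, t, x_mcp, y_mcp, x_pip, y_pip, x_tip, y_tip`,
#' compatible with typical video-tracking tool exports.
#'
#' @param track a `marker_track`.
#' @param path CSV file path.
#' @return `read_marker_track` returns a `marker_track`;
#'   `write_marker_track` returns `path` invisibly.
#' @export
write_marker_track <- function(track, path) {
  n <- nrow(track$markers)
  df <- data.frame(frame = seq_len(n) - 1L,
                   t = (seq_len(n) - 1L) / track$frame_rate,
                   track$markers)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_track
#' @export
read_marker_track <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_mcp", "y_mcp", "x_pip", "y_pip", "x_tip", "y_tip")
  if (!all(need %in% names(df)))
    stop("marker CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  rate <- if ("t" %in% names(df) && nrow(df) > 1L)
    1 / mean(diff(df$t)) else 1
  structure(list(markers = as.matrix(df[, need]), frame_rate = rate),
            class = "marker_track")
}

#' Compare two angle trajectories
#'
#' Linearly resamples both series onto the time grid of the coarser
#' (lower-rate) series over their overlapping time span, then reports the
#' per-frame difference `b - a` and summary metrics.
#'
#' @param a,b numeric angle series in degrees.
#' @param rate_a,rate_b frame rates (Hz) of `a` and `b`.
#' @param t0_a,t0_b start time (s) of each series; recordings that began at
#'   different moments are aligned on the absolute time axis.
#' @return Object of class `trajectory_comparison`: list with `time_s`,
#'   `a`, `b`, `difference` (all on the common grid), `rmse`, `max_abs`,
#'   `bias` (mean of `b - a`), degrees.
#' @export
compare_trajectories <- function(a, b, rate_a = 1, rate_b = rate_a,
                                 t0_a = 0, t0_b = 0) {
  stopifnot(length(a) >= 2L, length(b) >= 2L, rate_a > 0, rate_b > 0)
  ta <- t0_a + (seq_along(a) - 1) / rate_a
  tb <- t0_b + (seq_along(b) - 1) / rate_b
  t0 <- max(ta[1], tb[1]); t1 <- min(ta[length(ta)], tb[length(tb)])
  if (t1 <= t0)
    stop("trajectories have no overlapping time span", call. = FALSE)
  coarse <- if (rate_a <= rate_b) ta else tb
  grid <- coarse[coarse >= t0 & coarse <= t1]
  ar <- stats::approx(ta, a, xout = grid)$y
  br <- stats::approx(tb, b, xout = grid)$y
  d <- br - ar
  structure(list(time_s = grid, a = ar, b = br, difference = d,
                 rmse = sqrt(mean(d^2)), max_abs = max(abs(d)),
                 bias = mean(d)),
            class = "trajectory_comparison")
}

#' @export
print.trajectory_comparison <- function(x, ...) {
  cat(sprintf(paste0("trajectory_comparison over %d samples: ",
                     "rmse %.3f deg, max |diff| %.3f deg, bias %.3f deg\n"),
              length(x$difference), x$rmse, x$max_abs, x$bias))
  invisible(x)
}

#' Write a comparison report
#'
#' Persists the per-frame table as CSV and a plain-text summary alongside.
#'
#' @param comparison a `trajectory_comparison`.
#' @param path CSV path; the summary goes to `<path>.summary.txt`.
#' @param provenance optional provenance line for the summary.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path, provenance = NULL) {
  df <- data.frame(t = comparison$time_s, a = comparison$a, b = comparison$b,
                   difference = comparison$difference)
  utils::write.csv(df, path, row.names = FALSE)
  writeLines(c(
    "handmotion trajectory comparison",
    if (!is.null(provenance)) provenance,
    sprintf("samples: %d", length(comparison$difference)),
    sprintf("rmse_deg: %.6f", comparison$rmse),
    sprintf("max_abs_deg: %.6f", comparison$max_abs),
    sprintf("bias_deg: %.6f", comparison$bias)),
    paste0(path, ".summary.txt"))
  invisible(path)
}
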