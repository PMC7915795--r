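# 2D marker validation path: marker angles, synthetic camera projection and
# trajectory comparison.

test_that("angle_from_markers handles the canonical marker layouts", {
  expect_equal(angle_from_markers(c(0, 0), c(1, 0), c(2, 0)), 0)
  expect_equal(angle_from_markers(c(0, 0), c(1, 0), c(1, -1)), 90)
  # distal segment 30 degrees below the proximal line: oracle via atan2 of
  # the two direction vectors
  p3 <- c(1 + cos(-30 * pi / 180), sin(-30 * pi / 180))
  a1 <- atan2(0, 1)
  a2 <- atan2(p3[2] - 0, p3[1] - 1)
  oracle <- abs(a2 - a1) * 180 / pi
  expect_equal(angle_from_markers(c(0, 0), c(1, 0), p3), oracle,
               tolerance = 1e-9)
  expect_equal(oracle, 30, tolerance = 1e-9)
  expect_error(angle_from_markers(c(0, 0), c(0, 0), c(1, 1)),
               "degenerate markers")
})

test_that("marker angle is invariant under rigid motion and scaling", {
  set.seed(17)
  for (k in 1:50) {
    p <- matrix(stats::runif(6, -5, 5), 3, 2)
    base <- tryCatch(angle_from_markers(p[1, ], p[2, ], p[3, ]),
                     error = function(e) NA)
    if (is.na(base)) next
    th <- stats::runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    s <- stats::runif(1, 0.1, 10)
    shift <- stats::runif(2, -100, 100)
    q <- s * p %*% t(rot) + rep(shift, each = 3)
    expect_equal(angle_from_markers(q[1, ], q[2, ], q[3, ]), base,
                 tolerance = 1e-9)
  }
})

test_that("side-view marker angle equals the 3D Cardan flexion for planar motion", {
  rec <- pip_ramp_recording(n = 40, peak = 85)
  track <- project_recording(rec, digit = 2, view = "side")
  ang2d <- marker_angle_series(track)
  phi3d <- angle_series(compute_joint_angle_series(rec), "finger2_pip", "phi")
  expect_lt(max(abs(ang2d - phi3d)), 1e-6)
})

test_that("top view collapses marker separation as flexion grows", {
  rec <- pip_ramp_recording(n = 30, peak = 85)
  track <- project_recording(rec, digit = 2, view = "top")
  m <- track$markers
  d <- sqrt((m[, "x_tip"] - m[, "x_pip"])^2 + (m[, "y_tip"] - m[, "y_pip"])^2)
  expect_true(all(diff(d) < 0))
  # oracle: projected distance = chain length * cos(flexion)
  sk <- default_skeleton()
  chain <- sum(sk$bones$length_mm[sk$bones$name %in%
                                  c("finger2_intermediate", "finger2_distal")])
  phi <- seq(0, 85, length.out = 30)
  expect_equal(d, chain * cos(phi * pi / 180), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("zero motion projects to a constant track", {
  sk <- default_skeleton()
  rec <- forward_kinematics(sk, list(wrist = rep(0, 5)), 60)
  m <- project_recording(rec, 2, "side")$markers
  expect_equal(m, m[rep(1, 5), ], ignore_attr = TRUE)
})

test_that("marker tracks round-trip through CSV", {
  rec <- pip_ramp_recording(n = 12, peak = 60, rate = 30)
  track <- project_recording(rec, 2, "side")
  path <- withr::local_tempfile(fileext = ".csv")
  write_marker_track(track, path)
  back <- read_marker_track(path)
  expect_equal(back$markers, track$markers, tolerance = 1e-9)
  expect_equal(back$frame_rate, 30, tolerance = 1e-9)
  expect_error(read_marker_track({
    p <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(x = 1:3), p, row.names = FALSE); p
  }), "missing columns")
})

test_that("compare_trajectories reports difference metrics on a common grid", {
  a <- seq(0, 100, length.out = 50)
  same <- compare_trajectories(a, a, 50, 50)
  expect_equal(same$rmse, 0)
  expect_equal(same$max_abs, 0)
  expect_equal(same$bias, 0)
  off <- compare_trajectories(a, a + 10, 50, 50)
  expect_equal(off$bias, 10)
  expect_equal(off$rmse, 10)
  expect_equal(off$max_abs, 10)
  # clipped at 80: the saturation pattern, peak error at the ramp top
  clip <- compare_trajectories(a, pmin(a, 80), 50, 50)
  expect_equal(clip$max_abs, 20)
  expect_equal(min(clip$difference), -20)
  expect_true(clip$rmse <= clip$max_abs)
})

test_that("comparison resamples to the coarser rate and is symmetric", {
  # same underlying ramp sampled at 100 Hz and 40 Hz
  t_fast <- seq(0, 1, by = 1 / 100)
  t_slow <- seq(0, 1, by = 1 / 40)
  a <- 100 * t_fast
  b <- 100 * t_slow + 5
  ab <- compare_trajectories(a, b, 100, 40)
  expect_length(ab$difference, length(t_slow))
  expect_equal(ab$bias, 5, tolerance = 1e-9)
  ba <- compare_trajectories(b, a, 40, 100)
  expect_equal(ba$rmse, ab$rmse, tolerance = 1e-9)
  expect_equal(ba$max_abs, ab$max_abs, tolerance = 1e-9)
  expect_equal(ba$bias, -ab$bias, tolerance = 1e-9)
  expect_error(compare_trajectories(a, b, 1e6, 1e-6), NA) # overlap exists
})

test_that("disjoint time spans are rejected", {
  a <- 1:10; b <- 1:10
  expect_error(compare_trajectories(a, b, 1, 1, t0_a = 0, t0_b = 100),
               "no overlapping time span")
  expect_error(compare_trajectories(numeric(1), b), "length")
  # a shifted-but-overlapping pair still works
  ok <- compare_trajectories(a, b, 1, 1, t0_a = 0, t0_b = 5)
  expect_length(ok$difference, 5L)
})
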