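# Driver vector files, normalized time series and finger-length extraction.

test_that("make_time_series spans 0..1 with constant spacing", {
  expect_equal(make_time_series(2), c(0, 1))
  expect_equal(make_time_series(5), c(0, 0.25, 0.5, 0.75, 1))
  for (n in c(3, 7, 50)) {
    ts <- make_time_series(n)
    expect_length(ts, n)
    expect_equal(ts[1], 0)
    expect_equal(ts[n], 1)
    expect_equal(diff(ts), rep(1 / (n - 1), n - 1))
  }
  expect_error(make_time_series(1), "n_frames")
})

test_that("all-zero series export all-zero vectors of frame-count length", {
  sk <- default_skeleton()
  set <- compute_joint_angle_series(
    forward_kinematics(sk, list(wrist = rep(0, 5)), 60))
  dir <- withr::local_tempdir()
  written <- export_driver_files(set, dir)
  files <- c(sprintf("Finger%d.any", 1:5), "Wrist.any", "Elbow.any",
             "TimeSeries.any")
  expect_true(all(file.exists(file.path(dir, files))))
  for (part in setdiff(files, "TimeSeries.any")) {
    vecs <- read_driver_file(file.path(dir, part))
    expect_gt(length(vecs), 0)
    for (v in vecs) {
      expect_length(v, 5L)
      expect_equal(v, rep(0, 5))
    }
  }
  expect_equal(read_driver_file(file.path(dir, "TimeSeries.any"))[[1]],
               c(0, 0.25, 0.5, 0.75, 1))
})

test_that("DOF masks select the exported vectors", {
  sk <- default_skeleton()
  set <- compute_joint_angle_series(
    forward_kinematics(sk, list(wrist = c(0, 5)), 60))
  dir <- withr::local_tempdir()
  export_driver_files(set, dir)
  f2 <- read_driver_file(file.path(dir, "Finger2.any"))
  # index finger: MCP flexion+abduction, PIP flexion, DIP flexion; CMC rigid
  expect_setequal(names(f2), c("Finger2.Joint_MC_PP.Flexion",
                               "Finger2.Joint_MC_PP.Abduction",
                               "Finger2.Joint_PP_IP.Flexion",
                               "Finger2.Joint_IP_DP.Flexion"))
  elbow <- read_driver_file(file.path(dir, "Elbow.any"))
  expect_setequal(names(elbow), c("Elbow.Joint_Global_Forearm.Flexion",
                                  "Elbow.Joint_Global_Forearm.Rotation"))
  wrist <- read_driver_file(file.path(dir, "Wrist.any"))
  expect_setequal(names(wrist), c("Wrist.Joint_Forearm_Carpus.Flexion",
                                  "Wrist.Joint_Forearm_Carpus.Abduction"))
  f1 <- read_driver_file(file.path(dir, "Finger1.any"))
  expect_true("Finger1.Joint_Carpus_MC.Rotation" %in% names(f1)) # thumb CMC
})

test_that("fist-scenario drivers reproduce the input trajectory through the pipeline", {
  sk <- default_skeleton()
  truth <- fist_scenario(sk, 40, 100)
  rec <- forward_kinematics(sk, truth, 60)
  set <- compute_joint_angle_series(rec)
  dir <- withr::local_tempdir()
  written <- export_driver_files(set, dir, provenance = "seed=1")
  f2 <- read_driver_file(file.path(dir, "Finger2.any"))
  expect_equal(f2[["Finger2.Joint_PP_IP.Flexion"]],
               truth$angles$finger2_pip[, "phi"], tolerance = 1e-4)
  # parse-back reproduces the in-memory vectors exactly at text precision
  for (fname in names(written)) {
    back <- read_driver_file(file.path(dir, fname))
    expect_identical(lapply(back, round, 6),
                     lapply(written[[fname]],
                            function(v) round(unname(v), 6)))
  }
})

test_that("driver values match BVH channels after channel-order unmapping", {
  sk <- default_skeleton()
  rec <- forward_kinematics(sk, fist_scenario(sk, 15, 95), 60)
  set <- compute_joint_angle_series(rec)
  dir <- withr::local_tempdir()
  export_driver_files(set, dir)
  bvh_path <- file.path(dir, "motion.bvh")
  write_bvh(sk, set, 60, bvh_path)
  from_bvh <- read_bvh(bvh_path)$angles
  f3 <- read_driver_file(file.path(dir, "Finger3.any"))
  expect_equal(f3[["Finger3.Joint_PP_IP.Flexion"]],
               from_bvh$angles$finger3_pip[, "phi"], tolerance = 1e-4)
  expect_equal(f3[["Finger3.Joint_MC_PP.Abduction"]],
               from_bvh$angles$finger3_mcp[, "theta"], tolerance = 1e-4)
})

test_that("finger lengths equal the skeleton's segment lengths, scaling linearly", {
  for (scale in c(1, 1.2)) {
    sk <- default_skeleton("right", scale)
    rec <- forward_kinematics(sk, fist_scenario(sk, 6, 90), 60)
    fl <- compute_finger_lengths(rec)
    expect_equal(nrow(fl), 20L)
    expect_equal(fl$length_mm, sk$bones$length_mm[match(fl$bone, sk$bones$name)],
                 tolerance = 1e-9)
    expect_equal(fl$length_mm[fl$bone == "finger2_proximal"], 40 * scale,
                 tolerance = 1e-9)
  }
})

test_that("mean-over-frames estimator recovers lengths from noisy positions", {
  sk <- default_skeleton()
  rec <- forward_kinematics(sk, fist_scenario(sk, 100, 90), 60)
  noisy <- add_noise(rec, noise_spec(position_sigma = 0.5, seed = 99))
  fl <- compute_finger_lengths(noisy, estimator = "mean")
  truth <- sk$bones$length_mm[match(fl$bone, sk$bones$name)]
  # the zero-length thumb metacarpal is excluded: |noise| has a
  # non-vanishing mean, so averaging cannot remove its bias there
  real <- truth > 0
  expect_lt(max(abs(fl$length_mm - truth)[real]), 0.2)
  expect_lt(fl$length_mm[!real], 3 * 0.5 * sqrt(2)) # pure-noise segment
})

test_that("frame0 estimator on noisy data is noisier than the mean estimator", {
  sk <- default_skeleton()
  rec <- forward_kinematics(sk, fist_scenario(sk, 100, 90), 60)
  noisy <- add_noise(rec, noise_spec(position_sigma = 0.5, seed = 4))
  truth <- sk$bones$length_mm
  err_of <- function(fl) {
    t <- truth[match(fl$bone, sk$bones$name)]
    mean(abs(fl$length_mm - t)[t > 0])
  }
  expect_lt(err_of(compute_finger_lengths(noisy, "mean")),
            err_of(compute_finger_lengths(noisy, "frame0")))
})

test_that("FingerLength.any round-trips and unequal frame counts are rejected", {
  sk <- default_skeleton()
  rec <- forward_kinematics(sk, list(wrist = c(0, 10)), 60)
  set <- compute_joint_angle_series(rec)
  dir <- withr::local_tempdir()
  export_driver_files(set, dir, finger_lengths = compute_finger_lengths(rec))
  fl <- read_driver_file(file.path(dir, "FingerLength.any"))
  expect_equal(fl[["Finger2.Length_PP"]], 40, tolerance = 1e-6)
  expect_equal(fl[["Finger1.Length_MC"]], 0)
  broken <- set
  broken$angles$wrist <- broken$angles$wrist[1, , drop = FALSE]
  expect_error(export_driver_files(broken, dir), "frame count mismatch")
})
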