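# Phantom rendering, trajectory simulation, shapes, cohorts.

test_that("vessel_geometry enforces its invariants", {
  expect_s3_class(straight_tube(), "vessel_geometry")
  expect_error(vessel_geometry(cbind(c(0, 0), c(0, 0)), c(1, 1), 0,
                               c(0, 1), c(1, 2)), "strictly ordered")
  expect_error(vessel_geometry(cbind(0:10, 0), rep(-1, 11), 5,
                               c(0, 5), c(5, 9)), "radii")
  # valve radius must be the global minimum
  r <- rep(10, 11); r[3] <- 4
  expect_error(vessel_geometry(cbind(0:10, 0), r, 9, c(0, 5), c(5, 9)),
               "global minimum")
  # overlapping stage spans rejected
  expect_error(vessel_geometry(cbind(0:10, 0), rep(10, 11), 5,
                               c(0, 6), c(5, 9)), "disjoint")
})

test_that("phantom mask matches the noise-free tube geometry", {
  g <- straight_tube(len = 100, radius = 10, cy = 30, x0 = 15)
  ph <- make_phantom(g, width = 140, height = 60, fg_intensity = 200,
                     bg_intensity = 50, noise_sd = 0)
  # interior columns: rows within +/- 10 px of the centerline, nothing else
  for (x in c(40, 70, 100)) {
    col <- ph$mask[, x + 1]
    expect_identical(which(col) - 1L, 20:40)  # cy=30 +/- 10
  }
  # separable intensities: threshold 125 recovers ground truth exactly
  expect_identical(binarize(ph$image, 125), ph$mask)
})

test_that("default arch mask equals the brute-force point-in-tube oracle", {
  g <- aorta_geometry(scale = 0.25)
  cs <- canvas_size(0.25)
  ph <- make_phantom(g, width = cs[1], height = cs[2])
  # brute force: pixel is lumen iff within radius of some centerline point
  px <- rep(0:(cs[1] - 1), each = cs[2])
  py <- rep(0:(cs[2] - 1), times = cs[1])
  inside <- rep(FALSE, length(px))
  cl <- g$centerline; rad <- g$radius
  for (j in seq_len(nrow(cl))) {
    d2 <- (px - cl[j, 1])^2 + (py - cl[j, 2])^2
    inside <- inside | d2 <= rad[j]^2
  }
  oracle <- matrix(inside, nrow = cs[2], ncol = cs[1])
  expect_identical(unname(ph$mask), oracle)
})

test_that("geometry exceeding the frame is rejected with the offending point", {
  g <- straight_tube(len = 100, radius = 10, cy = 5)  # tube sticks out on top
  expect_error(make_phantom(g, width = 140, height = 60), "centerline point")
})

test_that("trajectory simulation is deterministic and lumen-bounded", {
  g <- aorta_geometry(scale = 0.5)
  p <- default_profiles()$novice$conventional
  r1 <- simulate_trajectory(g, p, seed = 11)
  r2 <- simulate_trajectory(g, p, seed = 11)
  expect_identical(r1, r2)

  # with tremor off, every sample lies inside the ground-truth lumen
  p0 <- motion_profile(10, pause_fraction = 0.2, tremor_sd = 0,
                       correction_prob = 0.3, lateral_sd = 3)
  run <- simulate_trajectory(g, p0, seed = 3)
  cs <- canvas_size(0.5)
  mask <- make_phantom(g, width = cs[1], height = cs[2])$mask
  ij <- cbind(round(run$trajectory$y_px) + 1, round(run$trajectory$x_px) + 1)
  expect_true(all(mask[ij]))

  # stage 1 ends where stage 2 begins; both inside the time span
  expect_equal(run$stages$stage1[2], run$stages$stage2[1])
  expect_lte(run$stages$stage2[2], max(run$trajectory$time_s))
})

test_that("a single pause-free sub-movement reproduces the minimum-jerk pulse", {
  g <- straight_tube(len = 400, radius = 12, cy = 40, x0 = 10)
  p <- motion_profile(1, mean_submovement_duration = 2, pause_fraction = 0,
                      tremor_sd = 0, correction_prob = 0, lateral_sd = 0)
  run <- simulate_trajectory(g, p, dt = 1 / 200, seed = 5)
  tr <- run$trajectory
  # pure progression along the centerline: y constant, x monotone
  expect_equal(max(abs(tr$y_px - 40)), 0, tolerance = 1e-9)
  expect_true(all(diff(tr$x_px) >= -1e-9))
  jd <- dimensionless_jerk(tr, c(0, max(tr$time_s)), dt = 1 / 200)
  expect_equal(jd, 360, tolerance = 0.02)
})

test_that("expert profiles beat novice profiles on stage-1 time and jerk", {
  g <- aorta_geometry(scale = 0.5)
  cs <- canvas_size(0.5)
  dist <- distance_image(make_phantom(g, width = cs[1], height = cs[2])$mask)
  p <- default_profiles()
  wins_t <- wins_j <- 0
  n_pairs <- 20
  for (i in seq_len(n_pairs)) {
    re <- simulate_trajectory(g, p$expert$conventional, seed = i)
    rn <- simulate_trajectory(g, p$novice$conventional, seed = 1000 + i)
    fe <- extract_features(re$trajectory, re$stages, dist)
    fn <- extract_features(rn$trajectory, rn$stages, dist)
    wins_t <- wins_t + (fe$T_p[1] < fn$T_p[1])
    wins_j <- wins_j + (fe$j_d[1] < fn$j_d[1])
  }
  expect_gte(wins_t, 0.95 * n_pairs)
  expect_gte(wins_j, 0.95 * n_pairs)
})

test_that("shape annotations resample the trailing catheter uniformly", {
  g <- straight_tube(len = 200, radius = 10, cy = 30, x0 = 0)
  # tip exactly 100 px in
  traj <- data.frame(frame = 0:1, time_s = c(0, 1),
                     x_px = c(0, 100), y_px = c(30, 30))
  sh <- make_shape_annotations(traj, g, n_points = 11, frames = 1L)
  expect_equal(sh[["1"]][, 1], seq(0, 100, by = 10))
  expect_equal(sh[["1"]][, 2], rep(30, 11))

  # tip at the insertion point: degenerate coincident polyline
  sh0 <- make_shape_annotations(traj, g, n_points = 5, frames = 0L)
  expect_equal(nrow(sh0[["0"]]), 5)
  expect_equal(max(dist(sh0[["0"]])), 0)

  # every annotated frame has the same number of points
  run <- simulate_trajectory(aorta_geometry(scale = 0.5),
                             default_profiles()$expert$conventional, seed = 2)
  shapes <- make_shape_annotations(run$trajectory, aorta_geometry(scale = 0.5),
                                   n_points = 15, frame_stride = 10)
  expect_true(all(vapply(shapes, nrow, integer(1)) == 15L))

  expect_error(make_shape_annotations(traj, g, n_points = 11, frames = 99L),
               "beyond trajectory")
})

test_that("rendered video is phantom plus a local tip stamp", {
  g <- straight_tube(len = 60, radius = 8, cy = 20, x0 = 10)
  ph <- make_phantom(g, width = 90, height = 40)
  traj <- data.frame(frame = 0:2, time_s = c(0, 0.04, 0.08),
                     x_px = c(20, 20, 35.3), y_px = c(20, 20, 22.1))
  vid <- render_video(ph$image, traj, tip_radius = 3)
  expect_length(vid, 3)
  expect_identical(vid[[1]], vid[[2]])  # stationary tip: identical frames
  # frame 3 differs from the phantom only near the tip
  delta <- which(vid[[3]] != ph$image, arr.ind = TRUE)
  d <- sqrt((delta[, 2] - 1 - 35.3)^2 + (delta[, 1] - 1 - 22.1)^2)
  expect_true(all(d <= 4))  # tip_radius + 1
  expect_error(render_video(ph$image, data.frame(x_px = 2, y_px = 2),
                            tip_radius = 3), "outside")
})

test_that("cohort has one execution per subject and equipment, reproducibly", {
  g <- aorta_geometry(scale = 0.5)
  co <- simulate_cohort(n_expert = 2, n_novice = 2, geometry = g, seed = 9)
  expect_equal(nrow(co$subjects), 8)  # 4 subjects x 2 equipment
  expect_equal(as.integer(table(co$subjects$equipment)), c(4L, 4L))
  expect_true(all(table(co$subjects$subject_id) == 2L))
  co2 <- simulate_cohort(n_expert = 2, n_novice = 2, geometry = g, seed = 9)
  expect_identical(co$subjects, co2$subjects)
  expect_identical(co$executions, co2$executions)
})

test_that("robotic executions take longer than conventional within group", {
  g <- aorta_geometry(scale = 0.5)
  cs <- canvas_size(0.5)
  dist <- distance_image(make_phantom(g, width = cs[1], height = cs[2])$mask)
  deltas <- vapply(1:10, function(i) {
    co <- simulate_cohort(n_expert = 2, n_novice = 2, geometry = g, seed = i)
    f <- cohort_features(co, dist)
    f1 <- f[f$stage == 1, ]
    median(f1$T_p[f1$equipment == "robotic"]) -
      median(f1$T_p[f1$equipment == "conventional"])
  }, numeric(1))
  expect_gt(median(deltas), 0)
})
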