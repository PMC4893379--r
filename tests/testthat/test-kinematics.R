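# Kinematic feature extraction.

test_that("uniform resampling preserves lines and bounds sinusoid error", {
  tt <- c(0, 0.3, 0.7, 1.1, 2)
  lin <- data.frame(frame = 0:4, time_s = tt, x_px = 3 * tt + 1, y_px = -tt)
  u <- resample_uniform(lin, 0.05)
  expect_equal(u$x_px, 3 * u$time_s + 1, tolerance = 1e-12)
  expect_equal(u$y_px, -u$time_s, tolerance = 1e-12)

  cons <- data.frame(time_s = tt, x_px = rep(2, 5), y_px = rep(7, 5))
  u2 <- resample_uniform(cons, 0.1)
  expect_true(all(u2$x_px == 2) && all(u2$y_px == 7))

  # sinusoid: linear-interpolation error bound (2 pi f dt)^2 / 8 * amplitude
  f <- 2; A <- 10; dt0 <- 1 / 100
  t0 <- seq(0, 1, by = dt0)
  sin_traj <- data.frame(time_s = t0, x_px = A * sin(2 * pi * f * t0),
                         y_px = 0 * t0)
  u3 <- resample_uniform(sin_traj, 1 / 333)
  err <- max(abs(u3$x_px - A * sin(2 * pi * f * u3$time_s)))
  expect_lte(err, (2 * pi * f * dt0)^2 / 8 * A + 1e-12)

  expect_error(resample_uniform(lin, 10), "span")
})

test_that("smoothing reproduces low-order polynomials and shrinks noise", {
  tt <- seq(0, 1, by = 0.01)
  cubic <- data.frame(time_s = tt, x_px = 1 + tt - 2 * tt^2 + 0.5 * tt^3,
                      y_px = tt^2)
  s <- smooth_trajectory(cubic, window = 9, order = 3)
  expect_equal(s$x_px, cubic$x_px, tolerance = 1e-9)
  expect_equal(s$y_px, cubic$y_px, tolerance = 1e-9)

  set.seed(41)
  noise <- data.frame(time_s = tt, x_px = rnorm(length(tt)),
                      y_px = rnorm(length(tt)))
  sn <- smooth_trajectory(noise, window = 11, order = 2)
  expect_lt(var(sn$x_px), var(noise$x_px))
  expect_error(smooth_trajectory(noise, window = 8, order = 3), "odd")
  expect_error(smooth_trajectory(noise[1:5, ], window = 9, order = 3),
               "sample count")
})

test_that("time, path length and speed follow path (not displacement) semantics", {
  tt <- seq(0, 10, by = 0.5)
  straight <- data.frame(time_s = tt, x_px = 10 * tt, y_px = 0 * tt)
  expect_equal(procedure_time(c(0, 10)), 10)
  expect_equal(path_length(straight, c(0, 10)), 100)
  expect_equal(average_speed(straight, c(0, 10)), 10)

  stationary <- data.frame(time_s = tt, x_px = rep(5, 21), y_px = rep(5, 21))
  expect_equal(path_length(stationary, c(0, 10)), 0)
  expect_equal(average_speed(stationary, c(0, 10)), 0)

  # 50 px out and 50 px back: PL = 100 even though displacement is 0
  x <- c(seq(0, 50, by = 5), seq(45, 0, by = -5))
  bf <- data.frame(time_s = tt, x_px = x, y_px = 0 * tt)
  expect_equal(path_length(bf, c(0, 10)), 100)
  expect_equal(average_speed(bf, c(0, 10)), 10)
  expect_error(path_length(straight, c(5, 5)), "empty")
})

test_that("average acceleration is exact on quadratics and composes magnitudes", {
  tt <- seq(0, 2, by = 1 / 100)
  quad <- data.frame(time_s = tt, x_px = 0.5 * 3 * tt^2, y_px = 0.5 * 4 * tt^2)
  a <- average_acceleration(quad, c(0, 2), dt = 1 / 100, window = NULL)
  expect_equal(a, 5, tolerance = 1e-6)  # ax=3, ay=4 -> magnitude 5

  lin <- data.frame(time_s = tt, x_px = 7 * tt, y_px = -2 * tt)
  expect_equal(average_acceleration(lin, c(0, 2), dt = 1 / 100), 0,
               tolerance = 1e-8)
  expect_error(average_acceleration(quad[1:3, ], c(0, 0.02), dt = 0.01),
               "samples")
})

test_that("dimensionless jerk hits the closed-form 360 for minimum-jerk pulses", {
  for (prm in list(c(1, 0.5), c(123, 1.7), c(40, 3))) {
    tr <- min_jerk_traj(A = prm[1], T = prm[2], dt = 1e-3)
    jd <- dimensionless_jerk(tr, c(0, prm[2]), dt = 1e-3)
    expect_equal(jd, 360, tolerance = 0.01)
  }
  # discretization error decreases monotonically over a decade of dt
  errs <- vapply(c(0.01, 0.005, 0.002, 0.001), function(dt) {
    tr <- min_jerk_traj(A = 1, T = 1, dt = dt)
    abs(dimensionless_jerk(tr, c(0, 1), dt = dt) - 360)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("dimensionless jerk vanishes on constant velocity and is scale-free", {
  tt <- seq(0, 2, by = 0.01)
  lin <- data.frame(time_s = tt, x_px = 30 * tt, y_px = 10 * tt)
  expect_equal(dimensionless_jerk(lin, c(0, 2), dt = 0.01), 0,
               tolerance = 1e-12)

  set.seed(43)
  for (i in 1:10) {
    tr <- random_smooth_traj()
    j1 <- dimensionless_jerk(tr, c(0, 2), dt = 0.01)
    sc <- tr
    sc$x_px <- sc$x_px * 3; sc$y_px <- sc$y_px * 3; sc$time_s <- sc$time_s * 2
    j2 <- dimensionless_jerk(sc, c(0, 4), dt = 0.02)
    expect_equal(j2, j1, tolerance = 1e-6)
  }
  expect_error(dimensionless_jerk(
    data.frame(time_s = tt, x_px = rep(1, length(tt)), y_px = rep(1, length(tt))),
    c(0, 2), dt = 0.01), "path length")
})

test_that("time and path length are reversal-invariant", {
  set.seed(44)
  tr <- random_smooth_traj()
  rev_tr <- data.frame(frame = tr$frame, time_s = tr$time_s,
                       x_px = rev(tr$x_px), y_px = rev(tr$y_px))
  expect_equal(path_length(tr, c(0, 2)), path_length(rev_tr, c(0, 2)))
  expect_equal(procedure_time(c(0, 2)), 2)
})

test_that("wall distances reflect the tube geometry", {
  g <- straight_tube(len = 100, radius = 10, cy = 30, x0 = 15)
  ph <- make_phantom(g, width = 140, height = 60)
  d <- distance_image(ph$mask)
  tt <- seq(0, 4, by = 0.1)
  center <- data.frame(time_s = tt, x_px = seq(30, 90, length.out = length(tt)),
                       y_px = rep(30, length(tt)))
  d_tip <- tip_wall_distance(center, c(0, 4), d)
  expect_lte(abs(d_tip - 10), 1.05)  # centerline of a radius-10 tube

  # single point: its own (interpolated) distance
  one <- data.frame(time_s = c(0, 1), x_px = c(60, 60), y_px = c(30, 30))
  expect_equal(tip_wall_distance(one, c(0, 1), d),
               lookup_distances(d, rbind(c(60, 30)))[1])

  # a polyline hugging the wall is closer than the centerline track
  hug <- list(cbind(seq(30, 90, length.out = 20), rep(38, 20)))
  expect_lt(shape_wall_distance(hug, d), d_tip)
})

test_that("feature extraction is internally consistent across a cohort", {
  g <- aorta_geometry(scale = 0.5)
  cs <- canvas_size(0.5)
  dist <- distance_image(make_phantom(g, width = cs[1], height = cs[2])$mask)
  co <- simulate_cohort(n_expert = 3, n_novice = 3, geometry = g, seed = 17)
  f <- cohort_features(co, dist)
  expect_equal(nrow(f), 24)  # 6 subjects x 2 equipment x 2 stages
  expect_true(all(f$v_d * f$T_p - f$PL < 1e-9))
  expect_true(all(is.finite(f$T_p) & is.finite(f$j_d) & is.finite(f$a_d)))
  expect_true(all(f$T_p > 0 & f$PL > 0 & f$d_tip >= 0))
  # novice-expert contrast runs the expected way in stage 1
  f1 <- f[f$stage == 1 & f$equipment == "conventional", ]
  expect_lt(median(f1$j_d[f1$group == "expert"]),
            median(f1$j_d[f1$group == "novice"]))
})
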