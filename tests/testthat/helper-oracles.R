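# Independent oracles and fixture builders shared across test files.
# Every oracle here is written as directly as possible (brute force,
# enumeration, closed form) and never shares code with the package internals
# it checks.

# straight horizontal tube geometry: centerline y = cy, x in [x0, x0 + len]
straight_tube <- function(len = 300, radius = 10, cy = 50, x0 = 10,
                          step = 1) {
  xs <- seq(x0, x0 + len, by = step)
  vessel_geometry(
    centerline = cbind(xs, cy),
    radius_profile = rep(radius, length(xs)),
    valve_arclength = len,  # constant profile: min everywhere
    stage1_span = c(0, 0.7 * len),
    stage2_span = c(0.7 * len, 0.9 * len)
  )
}

# analytic single minimum-jerk movement along x, sampled at dt
min_jerk_traj <- function(A = 100, T = 1, dt = 1e-3, x0 = 0, y0 = 0) {
  tt <- seq(0, T, by = dt)
  tau <- tt / T
  data.frame(frame = seq_along(tt) - 1L, time_s = tt,
             x_px = x0 + A * (10 * tau^3 - 15 * tau^4 + 6 * tau^5),
             y_px = rep(y0, length(tt)))
}

# smooth random trajectory: spline through random control points
random_smooth_traj <- function(n_ctrl = 8, n = 201, T = 2, amp = 50) {
  tc <- seq(0, T, length.out = n_ctrl)
  tt <- seq(0, T, length.out = n)
  data.frame(
    frame = seq_len(n) - 1L, time_s = tt,
    x_px = spline(tc, runif(n_ctrl, 0, amp), xout = tt)$y,
    y_px = spline(tc, runif(n_ctrl, 0, amp), xout = tt)$y)
}

# O(N^2) brute-force Euclidean distance transform (loop over background pixels)
brute_force_edt <- function(mask) {
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  d <- matrix(0, nrow(mask), ncol(mask))
  if (nrow(fg) == 0L) return(d)
  best <- rep(Inf, nrow(fg))
  for (b in seq_len(nrow(bg))) {
    d2 <- (fg[, 1] - bg[b, 1])^2 + (fg[, 2] - bg[b, 2])^2
    best <- pmin(best, d2)
  }
  d[fg] <- sqrt(best)
  d
}

# exact Mann-Whitney p by direct enumeration with pairwise-comparison U
oracle_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  U_of <- function(ia) {
    av <- pooled[ia]; bv <- pooled[-ia]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_obs <- U_of(seq_len(n1))
  idx <- utils::combn(n1 + n2, n1, simplify = FALSE)
  us <- vapply(idx, U_of, numeric(1))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# exact Wilcoxon signed-rank p by direct 2^n sign enumeration
oracle_wilcoxon_p <- function(x, y) {
  d <- x - y; d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- numeric(2^n)
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code))[1:n]
    ws[code + 1] <- sum(r[bits == 1L])
  }
  eps <- 1e-9
  min(1, 2 * min(mean(ws <= w_obs + eps), mean(ws >= w_obs - eps)))
}

# exhaustive minimum within-cluster SSE over all 2-cluster bipartitions
oracle_min_sse <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    asg <- c(1L, as.integer(intToBits(code))[1:(n - 1)] + 1L)
    sse <- 0
    for (k in 1:2) {
      xs <- X[asg == k, , drop = FALSE]
      if (nrow(xs)) sse <- sse + sum(sweep(xs, 2, colMeans(xs))^2)
    }
    if (sse < best) best <- sse
  }
  best
}

# direct double-loop NCC (independent of the package's vectorized gather)
oracle_ncc <- function(template, frame, center, s) {
  r <- (nrow(template) - 1L) %/% 2L
  cx <- round(center[1]); cy <- round(center[2])
  tz <- template - mean(template)
  tn <- sqrt(sum(tz^2))
  best <- -Inf; boff <- c(0L, 0L)
  for (dy in -s:s) for (dx in -s:s) {
    P <- frame[(cy + dy - r):(cy + dy + r) + 1L, (cx + dx - r):(cx + dx + r) + 1L]
    pz <- P - mean(P)
    den <- tn * sqrt(sum(pz^2))
    sc <- if (den > 0) sum(tz * pz) / den else 0
    closer <- dx^2 + dy^2 < boff[1]^2 + boff[2]^2
    if (sc > best + 1e-12 || (abs(sc - best) <= 1e-12 && closer)) {
      best <- sc; boff <- c(dx, dy)
    }
  }
  list(offset = boff, score = best)
}

# small rendered tracking fixture shared by tracking tests
tracking_fixture <- function(seed = 7, noise_sd = 0) {
  g <- aorta_geometry(scale = 0.5)
  cs <- canvas_size(0.5)
  ph <- make_phantom(g, width = cs[1], height = cs[2])
  run <- simulate_trajectory(g, default_profiles()$expert$conventional,
                             dt = 0.04, seed = seed)
  set.seed(seed + 1)
  vid <- render_video(ph$image, run$trajectory, tip_radius = 5,
                      noise_sd = noise_sd)
  list(video = vid, truth = run$trajectory)
}
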