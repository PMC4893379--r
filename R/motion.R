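# Skill-conditioned catheter-tip trajectory simulator.
#
# Movement along the vessel centerline is modelled as a sequence of
# minimum-jerk sub-movements separated by pauses: skilled operators advance in
# few long smooth pulls with little idle time, novices in many short pulls
# with frequent pauses, tremor and overshoot corrections. Equipment enters as
# a pure speed scaling (robotic navigation is slower).

#' Construct a motion profile
#'
#' The parameter set governing one simulated execution.
#'
#' @param n_submovements Number of minimum-jerk sub-movements (>= 1).
#' @param mean_submovement_duration Mean sub-movement duration in s (at
#'   `speed_scale = 1`).
#' @param pause_fraction Fraction of total time spent stationary, in [0, 1).
#' @param tremor_sd White positional noise sd in px.
#' @param correction_prob Probability that a sub-movement overshoots and a
#'   corrective back-movement follows, in [0, 1].
#' @param lateral_sd Sd (px) of the smooth lateral deviation from the
#'   centerline (first-order autoregressive, coefficient 0.95).
#' @param speed_scale Unitless speed multiplier; < 1 slows all sub-movements
#'   down (the equipment effect).
#' @return An object of class `motion_profile`.
#' @export
motion_profile <- function(n_submovements,
                           mean_submovement_duration = 1.0,
                           pause_fraction = 0.1,
                           tremor_sd = 0.5,
                           correction_prob = 0.05,
                           lateral_sd = 3,
                           speed_scale = 1.0) {
  if (n_submovements < 1) stop_cathkin("n_submovements must be >= 1")
  if (pause_fraction < 0 || pause_fraction >= 1)
    stop_cathkin("pause_fraction must be in [0, 1)")
  if (mean_submovement_duration <= 0 || speed_scale <= 0)
    stop_cathkin("durations and speed_scale must be positive")
  if (tremor_sd < 0 || lateral_sd < 0 || correction_prob < 0 || correction_prob > 1)
    stop_cathkin("invalid noise/correction parameters")
  structure(list(
    n_submovements = as.integer(round(n_submovements)),
    mean_submovement_duration = mean_submovement_duration,
    pause_fraction = pause_fraction,
    tremor_sd = tremor_sd,
    correction_prob = correction_prob,
    lateral_sd = lateral_sd,
    speed_scale = speed_scale
  ), class = "motion_profile")
}

#' Default motion profiles per experience group and equipment
#'
#' Experts advance in few smooth sub-movements with little idle time; novices
#' in many short ones with long pauses, larger tremor and frequent overshoot
#' corrections. The robotic condition halves effective speed. The defaults fix
#' the direction (not the magnitude) of the group contrasts observed in
#' phantom TAVI cannulation.
#'
#' @return Named list `expert` / `novice`, each with `conventional` and
#'   `robotic` [motion_profile()]s.
#' @export
default_profiles <- function() {
  base <- list(
    expert = list(n_submovements = 6, pause_fraction = 0.05,
                  tremor_sd = 0.5, correction_prob = 0.05),
    novice = list(n_submovements = 18, pause_fraction = 0.35,
                  tremor_sd = 1.5, correction_prob = 0.4)
  )
  lapply(base, function(p) list(
    conventional = motion_profile(p$n_submovements,
                                  pause_fraction = p$pause_fraction,
                                  tremor_sd = p$tremor_sd,
                                  correction_prob = p$correction_prob,
                                  speed_scale = 1.0),
    robotic = motion_profile(p$n_submovements,
                             pause_fraction = p$pause_fraction,
                             tremor_sd = p$tremor_sd,
                             correction_prob = p$correction_prob,
                             speed_scale = 0.5)
  ))
}

#' Simulate a catheter-tip trajectory along a vessel
#'
#' Arc-length progress along the centerline is the sum of minimum-jerk
#' sub-movement displacement profiles separated by pauses; a smooth
#' autoregressive lateral offset (clipped to stay inside the lumen) and white
#' tremor are added in image coordinates. Sub-movements may overshoot and be
#' followed by a corrective back-movement. The run starts at the beginning of
#' stage 1 and advances past the end of stage 2 into the ventricle; stage
#' boundary times are the first crossings of the stage arc-length limits.
#'
#' @param geometry A [vessel_geometry()].
#' @param profile A [motion_profile()].
#' @param dt Sampling interval in s (default 1/25, PAL video rate).
#' @param seed Integer seed for reproducibility, or `NULL` to consume the
#'   current RNG stream.
#' @return List with `trajectory` (data frame `frame`, `time_s`, `x_px`,
#'   `y_px`) and `stages` (list `stage1 = c(t0, t1)`, `stage2 = c(t0, t1)` in
#'   s, contiguous at the stage boundary).
#' @export
simulate_trajectory <- function(geometry, profile, dt = 1 / 25, seed = NULL) {
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(profile, "motion_profile"))
  if (dt <= 0) stop_cathkin("dt must be > 0")
  with_seed(seed, {
    arc_max <- geometry$arclength[length(geometry$arclength)]
    s_start <- geometry$stage1_span[1]
    s_end <- min(geometry$stage2_span[2] + 0.1 * diff(geometry$stage2_span),
                 arc_max - 1e-6)
    D <- s_end - s_start
    if (D <= 0) stop_cathkin("profile/geometry imply zero total displacement")

    n <- profile$n_submovements
    w <- stats::rgamma(n, shape = 4)
    amp <- D * w / sum(w)
    dur <- profile$mean_submovement_duration *
      stats::rlnorm(n, 0, 0.2) / profile$speed_scale

    # sub-movements, with overshoot + correction pairs where drawn
    amps <- numeric(0); durs <- numeric(0)
    over <- stats::runif(n) < profile$correction_prob
    ofrac <- stats::runif(n, 0.1, 0.3)
    for (j in seq_len(n)) {
      if (over[j]) {
        amps <- c(amps, amp[j] * (1 + ofrac[j]), -amp[j] * ofrac[j])
        durs <- c(durs, dur[j], 0.5 * profile$mean_submovement_duration /
                                 profile$speed_scale)
      } else {
        amps <- c(amps, amp[j])
        durs <- c(durs, dur[j])
      }
    }

    # pauses after each movement, totalling pause_fraction of total time
    active <- sum(durs)
    total_pause <- active * profile$pause_fraction / (1 - profile$pause_fraction)
    m <- length(amps)
    gaps <- if (m > 1L) {
      g <- stats::rgamma(m - 1L, shape = 1)
      total_pause * g / sum(g)
    } else numeric(0)
    if (m == 1L && total_pause > 0) gaps <- numeric(0)  # single pull: no gap to pause in

    # event table: alternating move / pause
    ev_amp <- ev_dur <- numeric(0)
    for (j in seq_len(m)) {
      ev_amp <- c(ev_amp, amps[j]); ev_dur <- c(ev_dur, durs[j])
      if (j <= length(gaps) && gaps[j] > 0) {
        ev_amp <- c(ev_amp, 0); ev_dur <- c(ev_dur, gaps[j])
      }
    }
    t0 <- c(0, cumsum(ev_dur))[seq_along(ev_dur)]
    s0 <- s_start + c(0, cumsum(ev_amp))[seq_along(ev_amp)]
    total_time <- sum(ev_dur)

    t <- seq(0, total_time, by = dt)
    if (t[length(t)] < total_time - 1e-12) t <- c(t, total_time)
    idx <- pmax(findInterval(t, t0), 1L)
    tau <- (t - t0[idx]) / ev_dur[idx]
    s <- s0[idx] + ev_amp[idx] * min_jerk_profile(tau)
    s <- pmin(pmax(s, 0), arc_max - 1e-6)

    g <- geometry_at(geometry, s)
    N <- length(t)
    # smooth lateral offset: AR(1) with coefficient 0.95, stationary sd lateral_sd
    lat <- if (profile$lateral_sd > 0) {
      innov <- stats::rnorm(N, 0, profile$lateral_sd * sqrt(1 - 0.95^2))
      as.numeric(stats::filter(innov, 0.95, method = "recursive"))
    } else rep(0, N)
    clearance <- 2
    lim <- pmax(g$radius - clearance, 0.25)
    lat <- pmin(pmax(lat, -lim), lim)
    nx <- -g$ty; ny <- g$tx  # unit normal
    x <- g$x + lat * nx + stats::rnorm(N, 0, profile$tremor_sd)
    y <- g$y + lat * ny + stats::rnorm(N, 0, profile$tremor_sd)

    first_cross <- function(target) t[which(s >= target - 1e-9)[1]]
    t1_end <- first_cross(geometry$stage1_span[2])
    t2_end <- first_cross(geometry$stage2_span[2])
    stages <- list(stage1 = c(0, t1_end), stage2 = c(t1_end, t2_end))

    list(
      trajectory = data.frame(frame = seq_len(N) - 1L, time_s = t,
                              x_px = x, y_px = y),
      stages = stages
    )
  })
}

#' Per-frame trailing catheter-shape annotations
#'
#' For a subset of frames, traces the catheter body as the centerline from the
#' insertion point to the tip's current arc-length position, resampled to a
#' fixed number of points — the synthetic analogue of manual catheter-shape
#' annotation on fluoroscopy frames, which uses the same number of points in
#' every frame.
#'
#' @param trajectory Trajectory data frame (`frame`, `time_s`, `x_px`, `y_px`).
#' @param geometry A [vessel_geometry()].
#' @param n_points Points per polyline (>= 2).
#' @param frame_stride Annotate every `frame_stride`-th frame.
#' @param frames Optional explicit 0-based frame indices (overrides
#'   `frame_stride`).
#' @return Named list, one `n_points` x 2 matrix per annotated frame; names are
#'   the 0-based frame indices.
#' @export
make_shape_annotations <- function(trajectory, geometry, n_points = 15,
                                   frame_stride = 25, frames = NULL) {
  if (n_points < 2) stop_cathkin("n_points must be >= 2")
  N <- nrow(trajectory)
  if (is.null(frames)) frames <- seq(0L, N - 1L, by = frame_stride)
  if (any(frames < 0L | frames >= N))
    stop_cathkin(sprintf("frame index %d beyond trajectory (0..%d)",
                         frames[which(frames < 0L | frames >= N)[1]], N - 1L))
  cl <- geometry$centerline; arc <- geometry$arclength
  shapes <- lapply(frames, function(f) {
    i <- f + 1L
    d2 <- (cl[, 1] - trajectory$x_px[i])^2 + (cl[, 2] - trajectory$y_px[i])^2
    s_tip <- arc[which.min(d2)]
    ss <- seq(0, s_tip, length.out = n_points)
    if (s_tip <= 0) {
      matrix(rep(cl[1, ], each = n_points), ncol = 2)
    } else {
      cbind(stats::approx(arc, cl[, 1], xout = ss)$y,
            stats::approx(arc, cl[, 2], xout = ss)$y)
    }
  })
  names(shapes) <- as.character(frames)
  shapes
}

#' Simulate a full study cohort
#'
#' Generates one conventional and one robotic execution per subject. Subject
#' skill heterogeneity is modelled by lognormal jitter of the group-default
#' profile parameters (sub-movement count and duration, pause fraction,
#' tremor, correction probability) with a common between-subject sd.
#'
#' @param n_expert,n_novice Subjects per experience group (>= 1).
#' @param profiles Group/equipment profiles as from [default_profiles()].
#' @param geometry A [vessel_geometry()].
#' @param dt Sampling interval in s.
#' @param between_subject_sd Lognormal sd of the per-subject parameter jitter.
#' @param n_shape_points,shape_stride Catheter-shape annotation density.
#' @param seed Integer seed; fixes every draw in the cohort.
#' @return Object of class `cohort`: list with `subjects` (data frame
#'   `subject_id`, `group`, `equipment`, one row per execution), `executions`
#'   (list of `trajectory` / `stages` / `shapes` per row), `geometry`, `dt`.
#' @export
simulate_cohort <- function(n_expert = 6, n_novice = 6,
                            profiles = default_profiles(),
                            geometry = aorta_geometry(),
                            dt = 1 / 25, between_subject_sd = 0.15,
                            n_shape_points = 15, shape_stride = 25,
                            seed = NULL) {
  if (n_expert < 1 || n_novice < 1) stop_cathkin("group sizes must be >= 1")
  with_seed(seed, {
    subjects <- data.frame(
      subject_id = character(0), group = character(0), equipment = character(0),
      stringsAsFactors = FALSE)
    executions <- list()
    groups <- c(rep("expert", n_expert), rep("novice", n_novice))
    ids <- sprintf("S%02d", seq_along(groups))
    for (i in seq_along(groups)) {
      jit <- stats::rlnorm(5, 0, between_subject_sd)
      for (equip in c("conventional", "robotic")) {
        p0 <- profiles[[groups[i]]][[equip]]
        p <- motion_profile(
          n_submovements = max(1, round(p0$n_submovements * jit[1])),
          mean_submovement_duration = p0$mean_submovement_duration * jit[2],
          pause_fraction = min(p0$pause_fraction * jit[3], 0.9),
          tremor_sd = p0$tremor_sd * jit[4],
          correction_prob = min(p0$correction_prob * jit[5], 1),
          lateral_sd = p0$lateral_sd,
          speed_scale = p0$speed_scale)
        run <- simulate_trajectory(geometry, p, dt = dt, seed = NULL)
        shapes <- make_shape_annotations(run$trajectory, geometry,
                                         n_points = n_shape_points,
                                         frame_stride = shape_stride)
        subjects <- rbind(subjects, data.frame(
          subject_id = ids[i], group = groups[i], equipment = equip,
          stringsAsFactors = FALSE))
        executions[[length(executions) + 1L]] <-
          list(trajectory = run$trajectory, stages = run$stages, shapes = shapes)
      }
    }
    structure(list(subjects = subjects, executions = executions,
                   geometry = geometry, dt = dt), class = "cohort")
  })
}
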