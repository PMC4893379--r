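# Per-stage kinematic features of a tip trajectory.
#
# Features: procedure time T_p (s), path length PL (px), average speed
# v_d = PL / T_p (px/s; pauses lower it by construction), average acceleration
# magnitude a_d (px/s^2), dimensionless jerk j_d (unitless), and the mean
# distance to the vessel wall of the tip (d_tip) and of the annotated catheter
# shape (d_shape), both in px.
#
# Dimensionless jerk:
#   j_d = (0.5 * integral over the stage of x'''(t)^2 + y'''(t)^2 dt) * T_p^5 / PL^2
# The T_p^5 / PL^2 normalization makes it invariant to movement duration and
# amplitude; lower values mean smoother movement. A single ideal minimum-jerk
# movement has j_d = 360 (0.5 * int_0^1 (60 - 360 tau + 360 tau^2)^2 dtau).
#
# Derivatives are taken on a uniformly resampled, Savitzky-Golay-smoothed
# trajectory by central differences; raw pixel-quantized tracks would make the
# third derivative meaningless.

#' Resample a trajectory onto a uniform time grid
#'
#' Linear interpolation of x and y onto a uniform grid spanning exactly
#' `[t_min, t_max]`: the step is shrunk (never grown) from `dt` so that both
#' endpoints are grid points.
#'
#' @param traj Trajectory data frame (`time_s`, `x_px`, `y_px`).
#' @param dt Target (maximum) sampling interval in s.
#' @return Resampled trajectory data frame (`frame`, `time_s`, `x_px`, `y_px`).
#' @export
resample_uniform <- function(traj, dt) {
  if (dt <= 0) stop_cathkin("dt must be > 0")
  t0 <- traj$time_s[1]; t1 <- traj$time_s[nrow(traj)]
  if (dt > t1 - t0) stop_cathkin("dt larger than the trajectory time span")
  # exact-span grid: step shrunk (never grown) so both endpoints are kept
  n_steps <- ceiling((t1 - t0) / dt - 1e-9)
  tt <- seq(t0, t1, length.out = n_steps + 1L)
  data.frame(frame = seq_along(tt) - 1L, time_s = tt,
             x_px = stats::approx(traj$time_s, traj$x_px, xout = tt)$y,
             y_px = stats::approx(traj$time_s, traj$y_px, xout = tt)$y)
}

#' Savitzky-Golay smoothing of a trajectory
#'
#' Per-coordinate local least-squares polynomial smoothing; polynomials of
#' degree <= `order` pass through unchanged. Assumes a uniform time grid.
#'
#' @param traj Uniformly sampled trajectory data frame.
#' @param window Odd window length in samples (> `order`).
#' @param order Polynomial degree.
#' @return Smoothed trajectory data frame.
#' @export
smooth_trajectory <- function(traj, window = 9, order = 3) {
  if (window %% 2 == 0 || window <= order)
    stop_cathkin("window must be odd and greater than order")
  if (window > nrow(traj)) stop_cathkin("window exceeds the sample count")
  traj$x_px <- signal::sgolayfilt(traj$x_px, p = order, n = window)
  traj$y_px <- signal::sgolayfilt(traj$y_px, p = order, n = window)
  traj
}

# indices of the samples spanning [t0, t1]: nearest sample to each boundary
interval_indices <- function(traj, interval) {
  if (interval[2] <= interval[1]) stop_cathkin("empty stage interval")
  i0 <- which.min(abs(traj$time_s - interval[1]))
  i1 <- which.min(abs(traj$time_s - interval[2]))
  if (i1 <= i0) stop_cathkin("stage interval contains fewer than two samples")
  i0:i1
}

#' Procedure time of a stage
#' @param interval Length-2 numeric `c(t_start, t_end)` in s.
#' @return T_p = t_end - t_start (s).
#' @export
procedure_time <- function(interval) {
  if (interval[2] <= interval[1]) stop_cathkin("empty stage interval")
  interval[2] - interval[1]
}

#' Path length of a trajectory over a stage
#' @param traj Trajectory data frame.
#' @param interval Length-2 `c(t_start, t_end)` in s.
#' @return Sum of Euclidean steps between consecutive samples in the stage (px).
#' @export
path_length <- function(traj, interval) {
  ii <- interval_indices(traj, interval)
  sum(sqrt(diff(traj$x_px[ii])^2 + diff(traj$y_px[ii])^2))
}

#' Average speed over a stage
#' @inheritParams path_length
#' @return v_d = PL / T_p (px/s).
#' @export
average_speed <- function(traj, interval) {
  path_length(traj, interval) / procedure_time(interval)
}

# resample + smooth the slice of traj covering the interval
prep_uniform <- function(traj, interval, dt, window, order) {
  ii <- interval_indices(traj, interval)
  u <- resample_uniform(traj[ii, ], dt)
  if (!is.null(window) && window <= nrow(u))
    u <- smooth_trajectory(u, window = window, order = order)
  u
}

#' Average acceleration magnitude over a stage
#'
#' Central second differences per axis on the smoothed uniformly resampled
#' trajectory; returns the mean of the per-sample magnitudes
#' \eqn{\sqrt{a_x^2 + a_y^2}}.
#'
#' @param traj Trajectory data frame.
#' @param interval Stage interval `c(t_start, t_end)` (s).
#' @param dt Resampling interval (s).
#' @param window,order Savitzky-Golay parameters (`window = NULL` disables
#'   smoothing).
#' @return a_d in px/s^2.
#' @export
average_acceleration <- function(traj, interval, dt = 1 / 25,
                                 window = 9, order = 3) {
  u <- prep_uniform(traj, interval, dt, window, order)
  n <- nrow(u)
  if (n < 5L) stop_cathkin("need at least 5 uniform samples for acceleration")
  h <- (u$time_s[n] - u$time_s[1]) / (n - 1L)  # effective grid step
  i <- 2:(n - 1L)
  ax <- (u$x_px[i + 1L] - 2 * u$x_px[i] + u$x_px[i - 1L]) / h^2
  ay <- (u$y_px[i + 1L] - 2 * u$y_px[i] + u$y_px[i - 1L]) / h^2
  mean(sqrt(ax^2 + ay^2))
}

#' Dimensionless jerk over a stage
#'
#' Third derivatives by central differences on the smoothed uniform
#' trajectory; squared-jerk integral by the trapezoidal rule over the stage;
#' normalized by T_p^5 / PL^2 (PL of the same smoothed uniform trajectory),
#' making the measure independent of movement duration and amplitude.
#'
#' @inheritParams average_acceleration
#' @return j_d (unitless); 360 for a single ideal minimum-jerk movement.
#' @export
dimensionless_jerk <- function(traj, interval, dt = 1 / 25,
                               window = 9, order = 3) {
  u <- prep_uniform(traj, interval, dt, window, order)
  n <- nrow(u)
  if (n < 7L) stop_cathkin("need at least 7 uniform samples for jerk")
  Tp <- u$time_s[n] - u$time_s[1]
  PL <- sum(sqrt(diff(u$x_px)^2 + diff(u$y_px)^2))
  if (PL <= 1e-9 * max(1, abs(u$x_px), abs(u$y_px)))
    stop_cathkin("zero path length: dimensionless jerk undefined")
  h <- Tp / (n - 1L)  # effective grid step
  i <- 3:(n - 2L)
  jx <- (u$x_px[i + 2L] - 2 * u$x_px[i + 1L] + 2 * u$x_px[i - 1L] - u$x_px[i - 2L]) /
    (2 * h^3)
  jy <- (u$y_px[i + 2L] - 2 * u$y_px[i + 1L] + 2 * u$y_px[i - 1L] - u$y_px[i - 2L]) /
    (2 * h^3)
  # central differences lose 2 samples per edge; extend the integrand to the
  # interval boundaries with its nearest interior value so edge jerk (maximal
  # for a minimum-jerk pulse) is not dropped
  J <- jx^2 + jy^2
  integral <- trapz(c(u$time_s[1], u$time_s[i], u$time_s[n]),
                    c(J[1], J, J[length(J)]))
  0.5 * integral * Tp^5 / PL^2
}

#' Mean tip distance to the vessel wall over a stage
#' @param traj Trajectory data frame.
#' @param interval Stage interval (s).
#' @param dist A [distance_image()].
#' @return d_tip (px).
#' @export
tip_wall_distance <- function(traj, interval, dist) {
  ii <- interval_indices(traj, interval)
  mean(lookup_distances(dist, cbind(traj$x_px[ii], traj$y_px[ii])))
}

#' Mean catheter-shape distance to the vessel wall
#' @param shapes List of n x 2 polyline matrices (one per annotated frame).
#' @param dist A [distance_image()].
#' @return d_shape (px): mean over all points of all polylines.
#' @export
shape_wall_distance <- function(shapes, dist) {
  if (!length(shapes)) stop_cathkin("no shape annotations")
  pts <- do.call(rbind, shapes)
  mean(lookup_distances(dist, pts))
}

#' Extract the per-stage kinematic feature vector
#'
#' Assembles T_p, PL, v_d, a_d, j_d, d_tip and d_shape for both stages of one
#' execution. Shape annotations are attributed to a stage by their frame time.
#'
#' @param traj Trajectory data frame.
#' @param stages List `stage1 = c(t0, t1)`, `stage2 = c(t0, t1)` (s).
#' @param dist A [distance_image()].
#' @param shapes Named list of shape polylines (names = 0-based frame index);
#'   `NULL` yields `NA` for d_shape.
#' @param dt Resampling interval (s); also the frame interval of `shapes`.
#' @param window,order Savitzky-Golay parameters.
#' @return Data frame with one row per stage: `stage`, `T_p`, `PL`, `v_d`,
#'   `a_d`, `j_d`, `d_tip`, `d_shape`.
#' @export
extract_features <- function(traj, stages, dist, shapes = NULL,
                             dt = 1 / 25, window = 9, order = 3) {
  frame_dt <- if (nrow(traj) >= 2L) diff(traj$time_s[1:2]) else dt
  one <- function(stage_idx, interval) {
    Tp <- procedure_time(interval)
    # short stages are mildly upsampled so the derivative stencils fit; heavy
    # upsampling of linearly interpolated tracks would fabricate jerk at the
    # interpolation knots, so the factor is kept small
    dt_stage <- min(dt, Tp / 8)
    PL <- path_length(traj, interval)
    dsh <- NA_real_
    if (!is.null(shapes) && length(shapes)) {
      ft <- as.numeric(names(shapes)) * frame_dt
      sel <- shapes[ft >= interval[1] & ft < interval[2]]
      if (length(sel)) dsh <- shape_wall_distance(sel, dist)
    }
    data.frame(
      stage = stage_idx, T_p = Tp, PL = PL, v_d = PL / Tp,
      a_d = average_acceleration(traj, interval, dt_stage, window, order),
      j_d = dimensionless_jerk(traj, interval, dt_stage, window, order),
      d_tip = tip_wall_distance(traj, interval, dist),
      d_shape = dsh
    )
  }
  rbind(one(1L, stages$stage1), one(2L, stages$stage2))
}

#' Kinematic feature table for a whole cohort
#'
#' Runs [extract_features()] on every execution of a simulated (or assembled)
#' cohort against a common distance image.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dist A [distance_image()] of the vessel lumen.
#' @param dt,window,order Differentiation-pipeline parameters.
#' @return Data frame with one row per execution x stage: `subject_id`,
#'   `group`, `equipment`, `stage` and the seven feature columns.
#' @export
cohort_features <- function(cohort, dist, dt = 1 / 25, window = 9, order = 3) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(seq_len(nrow(cohort$subjects)), function(i) {
    ex <- cohort$executions[[i]]
    f <- extract_features(ex$trajectory, ex$stages, dist, ex$shapes,
                          dt = dt, window = window, order = order)
    cbind(cohort$subjects[rep(i, nrow(f)), , drop = FALSE], f,
          row.names = NULL)
  })
  do.call(rbind, rows)
}
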