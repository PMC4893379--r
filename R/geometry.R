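# Vessel phantom geometry: a centerline with a per-point lumen radius.
#
# Coordinate convention (used throughout the package): 0-based pixel centers,
# x = column increasing rightward, y = row increasing downward, origin at the
# top-left pixel center.

#' Construct a vessel geometry
#'
#' A vessel is described by an ordered centerline polyline and a lumen
#' half-width (radius) at every centerline point. The lumen is the union of
#' discs of the local radius centered on the centerline points, so a dense
#' centerline (~1 px spacing) yields a smooth tube. Two stage intervals mark
#' the arch-navigation and valve-crossing phases of the cannulation task as
#' arc-length spans along the centerline.
#'
#' @param centerline Numeric n x 2 matrix of (x, y) points in px, ordered along
#'   the vessel; consecutive points must be distinct.
#' @param radius_profile Numeric vector of n positive lumen radii (px).
#' @param valve_arclength Arc-length position (px) of the stenotic valve; the
#'   radius there must equal the global minimum of `radius_profile`.
#' @param stage1_span,stage2_span Length-2 numeric arc-length intervals (px);
#'   stage 1 must precede stage 2 and the two must not overlap.
#' @return An object of class `vessel_geometry`: list with `centerline`,
#'   `radius`, `arclength` (cumulative, starting at 0), `tangent` (unit
#'   tangents), `valve_arclength`, `stage1_span`, `stage2_span`.
#' @export
vessel_geometry <- function(centerline, radius_profile, valve_arclength,
                            stage1_span, stage2_span) {
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 2L || nrow(centerline) < 2L)
    stop_cathkin("centerline must be an n x 2 matrix with n >= 2")
  radius_profile <- as.numeric(radius_profile)
  if (length(radius_profile) != nrow(centerline))
    stop_cathkin("radius_profile length must match centerline rows")
  if (any(radius_profile <= 0)) stop_cathkin("all radii must be > 0")
  steps <- sqrt(rowSums(diff(centerline)^2))
  if (any(steps <= 0))
    stop_cathkin("centerline points must be strictly ordered (distinct consecutive points)")
  arclength <- c(0, cumsum(steps))

  r_valve <- stats::approx(arclength, radius_profile, xout = valve_arclength,
                           rule = 2)$y
  if (r_valve > min(radius_profile) + 1e-9)
    stop_cathkin("radius at valve_arclength must be the global minimum (stenosis)")

  stage1_span <- as.numeric(stage1_span); stage2_span <- as.numeric(stage2_span)
  if (length(stage1_span) != 2L || length(stage2_span) != 2L ||
      stage1_span[1] >= stage1_span[2] || stage2_span[1] >= stage2_span[2])
    stop_cathkin("stage spans must be increasing length-2 intervals")
  if (stage1_span[2] > stage2_span[1] + 1e-9)
    stop_cathkin("stage spans must be disjoint with stage 1 preceding stage 2")
  smax <- arclength[length(arclength)]
  if (stage2_span[2] > smax + 1e-9)
    stop_cathkin("stage2 span exceeds centerline length")

  # unit tangents by central differences along the polyline
  n <- nrow(centerline)
  tx <- c(centerline[2, 1] - centerline[1, 1],
          centerline[3:n, 1] - centerline[1:(n - 2L), 1],
          centerline[n, 1] - centerline[n - 1L, 1])
  ty <- c(centerline[2, 2] - centerline[1, 2],
          centerline[3:n, 2] - centerline[1:(n - 2L), 2],
          centerline[n, 2] - centerline[n - 1L, 2])
  nrm <- sqrt(tx^2 + ty^2)
  structure(list(
    centerline = centerline,
    radius = radius_profile,
    arclength = arclength,
    tangent = cbind(tx / nrm, ty / nrm),
    valve_arclength = valve_arclength,
    stage1_span = stage1_span,
    stage2_span = stage2_span
  ), class = "vessel_geometry")
}

#' Default type-I aortic-arch phantom geometry
#'
#' Builds the package's default vessel: a vertical descending limb (length
#' 200 px, radius 18 px), a semicircular arch (radius 120 px), an ascending
#' limb narrowing into a stenotic valve (radius 6 px), and a rounded ventricle
#' chamber beyond the valve, laid out on a 720 x 576 canvas. Stage 1 (arch
#' navigation) runs from the descending aorta to 40 px proximal to the valve
#' (2 cm at the assumed 20 px/cm scale); stage 2 (valve crossing) runs from
#' there into the ventricle.
#'
#' @param scale Positive multiplier applied to every pixel dimension; use
#'   values < 1 for quick small-canvas experiments.
#' @return A `vessel_geometry`. The matching canvas is
#'   `round(c(720, 576) * scale)` (see [canvas_size()]).
#' @export
aorta_geometry <- function(scale = 1) {
  stopifnot(scale > 0)
  s <- scale
  step <- min(1, s)  # ~1 px spacing between centerline samples

  # descending limb: (560, 460) up to (560, 260)
  y_desc <- seq(460 * s, 260 * s, by = -step)
  desc <- cbind(560 * s, y_desc)
  # arch: semicircle center (440, 260), radius 120, from theta=0 to pi (over the top)
  R <- 120 * s
  theta <- seq(0, pi, by = step / R)[-1L]
  arch <- cbind(440 * s + R * cos(theta), 260 * s - R * sin(theta))
  # ascending limb: (320, 260) down to the valve at (320, 420)
  y_asc <- seq(260 * s + step, 420 * s, by = step)
  asc <- cbind(320 * s, y_asc)
  # ventricle: continue to (320, 500) with widening radius (rounded chamber)
  y_ven <- seq(420 * s + step, 500 * s, by = step)
  ven <- cbind(320 * s, y_ven)

  cl <- rbind(desc, arch, asc, ven)
  steps <- sqrt(rowSums(diff(cl)^2))
  arc <- c(0, cumsum(steps))
  valve_arc <- arc[nrow(desc) + nrow(arch) + nrow(asc)]

  rad <- rep(18 * s, nrow(cl))
  taper <- arc >= valve_arc - 40 * s & arc <= valve_arc
  rad[taper] <- 18 * s + (6 - 18) * s * (arc[taper] - (valve_arc - 40 * s)) / (40 * s)
  post <- arc > valve_arc
  rad[post] <- pmin(6 * s + (40 - 6) * s * (arc[post] - valve_arc) / (60 * s), 40 * s)

  vessel_geometry(
    centerline = cl, radius_profile = rad, valve_arclength = valve_arc,
    stage1_span = c(0, valve_arc - 40 * s),
    stage2_span = c(valve_arc - 40 * s, valve_arc + 50 * s)
  )
}

#' Canvas size matching a geometry scale
#'
#' @param scale The scale passed to [aorta_geometry()].
#' @return Integer `c(width, height)` in px (default 720 x 576).
#' @export
canvas_size <- function(scale = 1) as.integer(round(c(720, 576) * scale))

# Interpolated centerline position / tangent / radius at arc length s (vectorized).
geometry_at <- function(geometry, s) {
  arc <- geometry$arclength
  s <- pmin(pmax(s, 0), arc[length(arc)])
  list(
    x = stats::approx(arc, geometry$centerline[, 1], xout = s)$y,
    y = stats::approx(arc, geometry$centerline[, 2], xout = s)$y,
    tx = stats::approx(arc, geometry$tangent[, 1], xout = s)$y,
    ty = stats::approx(arc, geometry$tangent[, 2], xout = s)$y,
    radius = stats::approx(arc, geometry$radius, xout = s)$y
  )
}
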