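# Rendering the vessel phantom and synthetic fluoroscopy-like frames.
# Images are numeric matrices [height rows, width cols] with intensities in
# 0..255; pixel (x, y) in the 0-based coordinate convention is `img[y+1, x+1]`.

#' Render a vessel phantom image
#'
#' Draws the lumen as a bright region on a dark background: every pixel whose
#' center lies within the local radius of a centerline point gets
#' `fg_intensity`, all others `bg_intensity`; optional i.i.d. Gaussian noise is
#' added on top (clipped to 0..255). The noise-free lumen is returned as the
#' ground-truth mask.
#'
#' @param geometry A [vessel_geometry()].
#' @param width,height Canvas size in px.
#' @param fg_intensity,bg_intensity Foreground/background grey levels (0-255),
#'   `fg_intensity > bg_intensity`.
#' @param noise_sd Gaussian noise standard deviation in intensity units
#'   (0 = noise free). Uses the current RNG state.
#' @return List with `image` (numeric matrix) and `mask` (logical matrix,
#'   `TRUE` = lumen).
#' @export
make_phantom <- function(geometry, width = 720L, height = 576L,
                         fg_intensity = 200, bg_intensity = 50, noise_sd = 0) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  if (fg_intensity <= bg_intensity)
    stop_cathkin("fg_intensity must exceed bg_intensity")
  cl <- geometry$centerline; rad <- geometry$radius
  bad <- which(cl[, 1] - rad < -0.5 | cl[, 1] + rad > width - 0.5 |
               cl[, 2] - rad < -0.5 | cl[, 2] + rad > height - 0.5)
  if (length(bad))
    stop_cathkin(sprintf(
      "geometry exceeds frame bounds at centerline point %d (x=%.1f, y=%.1f, r=%.1f)",
      bad[1], cl[bad[1], 1], cl[bad[1], 2], rad[bad[1]]))

  mask <- matrix(FALSE, nrow = height, ncol = width)
  for (j in seq_len(nrow(cl))) {
    cx <- cl[j, 1]; cy <- cl[j, 2]; r <- rad[j]
    xs <- max(0, ceiling(cx - r)):min(width - 1L, floor(cx + r))
    ys <- max(0, ceiling(cy - r)):min(height - 1L, floor(cy + r))
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    mask[ys + 1L, xs + 1L] <- mask[ys + 1L, xs + 1L] | (d2 <= r^2)
  }
  img <- matrix(bg_intensity, nrow = height, ncol = width)
  img[mask] <- fg_intensity
  if (noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, noise_sd)
    img <- pmin(pmax(img, 0), 255)
  }
  list(image = img, mask = mask)
}

#' Render a synthetic frame sequence with a moving catheter tip
#'
#' Stamps a dark disc (with a 1 px anti-aliased rim, as a slightly blurred
#' radio-opaque tip would appear on screen) at the catheter-tip position on
#' top of the phantom, one frame per trajectory sample.
#'
#' @param phantom Phantom image matrix (e.g. `make_phantom(...)$image`).
#' @param trajectory Trajectory data frame with columns `x_px`, `y_px`.
#' @param tip_intensity Grey level of the tip disc (darker than the lumen).
#' @param tip_radius Disc radius in px.
#' @param noise_sd Optional per-frame i.i.d. Gaussian noise sd (intensity
#'   units), added independently to every frame.
#' @return List of frame matrices, one per trajectory sample.
#' @export
render_video <- function(phantom, trajectory, tip_intensity = 20, tip_radius = 3,
                         noise_sd = 0) {
  h <- nrow(phantom); w <- ncol(phantom)
  x <- trajectory$x_px; y <- trajectory$y_px
  if (any(x - tip_radius < -0.5 | x + tip_radius > w - 0.5 |
          y - tip_radius < -0.5 | y + tip_radius > h - 0.5))
    stop_cathkin("trajectory tip disc falls outside the frame")
  lapply(seq_along(x), function(i) {
    f <- phantom
    xs <- ceiling(x[i] - tip_radius - 1):floor(x[i] + tip_radius + 1)
    ys <- ceiling(y[i] - tip_radius - 1):floor(y[i] + tip_radius + 1)
    xs <- xs[xs >= 0 & xs <= w - 1L]; ys <- ys[ys >= 0 & ys <= h - 1L]
    d <- sqrt(outer((ys - y[i])^2, (xs - x[i])^2, "+"))
    wgt <- pmin(pmax(tip_radius + 0.5 - d, 0), 1)  # anti-aliased edge
    sub <- f[ys + 1L, xs + 1L]
    f[ys + 1L, xs + 1L] <- (1 - wgt) * sub + wgt * tip_intensity
    if (noise_sd > 0) f <- pmin(pmax(f + stats::rnorm(length(f), 0, noise_sd), 0), 255)
    f
  })
}
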