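# Rectification of recorded-screen coordinates into the canonical frame.
#
# Recordings of the fluoroscopy monitor are taken by an external camera from
# an unfixed position; the four marked screen corners define a plane
# projective map onto the canonical 720 x 576 frame, so trajectories from
# different recordings become comparable. When the source quadrilateral is a
# parallelogram the map degenerates to the affine case.

#' Fit the screen-rectification transform
#'
#' Computes the unique plane projective map sending the four recorded screen
#' corners to the corners of the canonical rectangle `(0,0)`, `(W,0)`,
#' `(W,H)`, `(0,H)`.
#'
#' @param src_corners 4 x 2 matrix of recorded-image corner coordinates (px),
#'   ordered top-left, top-right, bottom-right, bottom-left.
#' @param dst_size Canonical size `c(width, height)` in px.
#' @return Object of class `screen_calibration`: list with `src_corners`,
#'   `dst_size`, `coefficients` (the 8 parameters a..h of the map
#'   `x' = (a x + b y + c) / (g x + h y + 1)`,
#'   `y' = (d x + e y + f) / (g x + h y + 1)`) and the 3 x 3 matrix `H`.
#' @export
fit_screen_transform <- function(src_corners, dst_size = c(720, 576)) {
  src <- as.matrix(src_corners)
  if (!all(dim(src) == c(4L, 2L))) stop_cathkin("src_corners must be 4 x 2")
  if (nrow(unique(src)) < 4L) stop_cathkin("src_corners must be distinct")
  # reject any collinear triple (degenerate quadrilateral)
  for (tri in utils::combn(4L, 3L, simplify = FALSE)) {
    p <- src[tri, ]
    area2 <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                 (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2]))
    if (area2 < 1e-9) stop_cathkin("src_corners contain collinear points")
  }
  W <- dst_size[1]; H <- dst_size[2]
  dst <- rbind(c(0, 0), c(W, 0), c(W, H), c(0, H))

  # 8 linear equations in (a,b,c,d,e,f,g,h)
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  p <- tryCatch(solve(A, b),
                error = function(e) stop_cathkin("degenerate corner configuration: ",
                                                 conditionMessage(e)))
  cal <- structure(list(
    src_corners = src, dst_size = as.numeric(dst_size),
    coefficients = p,
    H = matrix(c(p[1:3], p[4:6], p[7:8], 1), nrow = 3, byrow = TRUE)
  ), class = "screen_calibration")
  chk <- apply_transform(cal, src)
  if (max(abs(chk - dst)) > 1e-6)
    stop_cathkin("calibration failed to reproduce destination corners")
  cal
}

#' Apply a screen calibration to points
#'
#' Homogeneous projective application; point order is preserved and any
#' accompanying metadata (timestamps) is untouched by design — only
#' coordinates are passed in.
#'
#' @param calibration A [fit_screen_transform()] result.
#' @param points n x 2 matrix (or data frame) of (x, y) coordinates.
#' @return n x 2 matrix of canonical-frame coordinates.
#' @export
apply_transform <- function(calibration, points) {
  stopifnot(inherits(calibration, "screen_calibration"))
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop_cathkin("points must be n x 2")
  H <- calibration$H
  den <- H[3, 1] * pts[, 1] + H[3, 2] * pts[, 2] + H[3, 3]
  bad <- which(den <= 0)
  if (length(bad))
    stop_cathkin(sprintf("point %d maps to or beyond the plane at infinity", bad[1]))
  cbind((H[1, 1] * pts[, 1] + H[1, 2] * pts[, 2] + H[1, 3]) / den,
        (H[2, 1] * pts[, 1] + H[2, 2] * pts[, 2] + H[2, 3]) / den)
}

#' Invert a screen calibration
#'
#' @param calibration A `screen_calibration`.
#' @return A `screen_calibration` applying the inverse map (its `src_corners`
#'   are the canonical rectangle corners).
#' @export
invert_transform <- function(calibration) {
  stopifnot(inherits(calibration, "screen_calibration"))
  Hi <- solve(calibration$H)
  Hi <- Hi / Hi[3, 3]
  W <- calibration$dst_size[1]; H2 <- calibration$dst_size[2]
  structure(list(
    src_corners = rbind(c(0, 0), c(W, 0), c(W, H2), c(0, H2)),
    dst_size = calibration$dst_size,
    coefficients = c(t(Hi))[1:8],
    H = Hi
  ), class = "screen_calibration")
}
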