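# Phantom segmentation and the distance-to-wall image.
#
# The vessel lumen appears bright on the (grayscale) fluoroscopy image; a
# threshold binarization recovers it, and the Euclidean distance transform of
# the binary mask gives, for every lumen pixel, the distance to the nearest
# wall (background) pixel — the basis of the distance-to-wall safety metric.

#' Binarize a grayscale image
#'
#' Pixels with intensity strictly above the threshold become foreground
#' (lumen), all others background. `threshold = "auto"` picks the threshold
#' maximizing the between-class intensity variance over the image histogram
#' (Otsu's criterion).
#'
#' @param image Numeric matrix of intensities in 0..255.
#' @param threshold Numeric cut-off in 0..255, or `"auto"`.
#' @param largest_component If `TRUE`, keep only the largest 4-connected
#'   foreground component (cleanup for noisy images; off by default).
#' @return Logical matrix (`TRUE` = foreground).
#' @export
binarize <- function(image, threshold = "auto", largest_component = FALSE) {
  if (length(image) == 0L) stop_cathkin("empty image")
  if (identical(threshold, "auto")) threshold <- otsu_threshold(image)
  mask <- image > threshold
  if (largest_component) mask <- largest_component_mask(mask)
  mask
}

#' Otsu threshold of an image
#'
#' Exhaustive scan over integer bin boundaries 0..254 of the 256-bin histogram,
#' maximizing the between-class variance \eqn{w_0 w_1 (\mu_0 - \mu_1)^2}; ties
#' resolved toward the smallest threshold.
#'
#' @param image Numeric matrix of intensities in 0..255.
#' @return The selected threshold (integer-valued numeric).
#' @export
otsu_threshold <- function(image) {
  if (length(image) == 0L) stop_cathkin("empty image")
  v <- pmin(pmax(as.integer(round(image)), 0L), 255L)
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  lv <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * lv)
  mu_t <- mu[256]
  t_cand <- 1:255  # threshold t means classes [0..t-1] | [t..255]
  w0t <- w0[t_cand]; mut <- mu[t_cand]
  valid <- w0t > 0 & w0t < 1
  sb2 <- rep(-Inf, 255)
  sb2[valid] <- (mu_t * w0t[valid] - mut[valid])^2 / (w0t[valid] * (1 - w0t[valid]))
  (which.max(sb2) - 1L)  # threshold: fg is "> t", so t = class boundary - 1
}

largest_component_mask <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w); cur <- 0L
  for (start in seq_along(mask)) {
    if (!mask[start] || lab[start] != 0L) next
    cur <- cur + 1L
    frontier <- start; lab[start] <- cur
    while (length(frontier)) {
      r <- (frontier - 1L) %% h + 1L; cc <- (frontier - 1L) %/% h + 1L
      nb <- c(frontier[r > 1L] - 1L, frontier[r < h] + 1L,
              frontier[cc > 1L] - h, frontier[cc < w] + h)
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
  }
  if (cur == 0L) return(mask)
  best <- which.max(tabulate(lab[lab > 0L], nbins = cur))
  lab == best
}

#' Exact Euclidean distance image of a binary mask
#'
#' For every foreground pixel, the exact Euclidean distance between pixel
#' centers to the nearest background pixel; background pixels get 0. Computed
#' by the two-pass separable lower-envelope algorithm on integer squared
#' distances, so results are bit-identical to an all-pairs search.
#'
#' @param mask Logical matrix (`TRUE` = foreground/lumen).
#' @return Numeric matrix of distances in px (class `distance_image`).
#' @export
distance_image <- function(mask) {
  if (!any(!mask)) stop_cathkin("mask has no background pixel: no wall exists")
  h <- nrow(mask); w <- ncol(mask)
  BIG <- (h + w + 1L)^2

  # pass 1: per-column vertical distance to nearest background (in rows),
  # vectorized across columns
  g <- matrix(0L, h, w)
  INFD <- h + w + 1L
  g[1, ] <- ifelse(mask[1, ], INFD, 0L)
  if (h > 1L) for (r in 2:h) g[r, ] <- ifelse(mask[r, ], pmin(g[r - 1L, ] + 1L, INFD), 0L)
  if (h > 1L) for (r in (h - 1L):1L) g[r, ] <- pmin(g[r, ], g[r + 1L, ] + 1L)

  # pass 2: per-row 1-D lower envelope of parabolas over squared distances
  d2 <- matrix(0, h, w)
  f <- numeric(w); vbuf <- integer(w); zbuf <- numeric(w + 1L)
  for (r in 1:h) {
    f <- as.numeric(g[r, ])^2
    f[f >= INFD^2] <- BIG
    if (w == 1L) { d2[r, ] <- f; next }
    k <- 1L; vbuf[1L] <- 1L; zbuf[1L] <- -Inf; zbuf[2L] <- Inf
    for (q in 2:w) {
      repeat {
        vk <- vbuf[k]
        s <- ((f[q] + q * q) - (f[vk] + vk * vk)) / (2 * (q - vk))
        if (s <= zbuf[k] && k > 1L) { k <- k - 1L } else break
      }
      k <- k + 1L
      vbuf[k] <- q; zbuf[k] <- s; zbuf[k + 1L] <- Inf
    }
    k <- 1L
    out <- numeric(w)
    for (q in 1:w) {
      while (zbuf[k + 1L] < q) k <- k + 1L
      vk <- vbuf[k]
      out[q] <- (q - vk)^2 + f[vk]
    }
    d2[r, ] <- out
  }
  d <- sqrt(d2)
  d[!mask] <- 0
  structure(d, class = c("distance_image", "matrix", "array"))
}

#' Sample a distance image at sub-pixel points
#'
#' Bilinear interpolation of the distance grid at arbitrary (x, y) positions
#' (0-based pixel-center coordinates).
#'
#' @param dist A [distance_image()] (or any numeric matrix).
#' @param points n x 2 matrix or data frame of (x, y) coordinates.
#' @return Numeric vector of interpolated distances (px).
#' @export
lookup_distances <- function(dist, points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop_cathkin("points must be n x 2")
  h <- nrow(dist); w <- ncol(dist)
  x <- pts[, 1]; y <- pts[, 2]
  bad <- which(x < 0 | x > w - 1 | y < 0 | y > h - 1 | !is.finite(x) | !is.finite(y))
  if (length(bad))
    stop_cathkin(sprintf("point %d (%.2f, %.2f) is outside the image",
                         bad[1], x[bad[1]], y[bad[1]]))
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  dist <- unclass(dist)
  (1 - fy) * ((1 - fx) * dist[i00] + fx * dist[i01]) +
    fy * ((1 - fx) * dist[i10] + fx * dist[i11])
}
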