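# Semi-automated catheter-tip tracking by brute-force zero-normalized
# cross-correlation template matching. Frames where the best match score falls
# below a confidence threshold are flagged for re-seeding (the batch analogue
# of interactive bootstrapping at points of failure).

# full NCC score surface over the square offset window (row-major in
# (dy, dx) with dx varying fastest); zero-variance patches score 0
ncc_scores <- function(template, frame, center, search_radius) {
  r <- (nrow(template) - 1L) %/% 2L
  if (nrow(template) != ncol(template) || nrow(template) %% 2L == 0L)
    stop_cathkin("template must be square with odd side")
  if (search_radius < 1) stop_cathkin("search_radius must be >= 1")
  s <- as.integer(search_radius)
  h <- nrow(frame); w <- ncol(frame)
  cx <- as.integer(round(center[1])); cy <- as.integer(round(center[2]))
  if (cx - s - r < 0L || cx + s + r > w - 1L || cy - s - r < 0L || cy + s + r > h - 1L)
    stop_cathkin("search window extends beyond the frame")

  offs <- expand.grid(dx = -s:s, dy = -s:s)  # row-major: dx varies fastest
  rel <- as.matrix(expand.grid(py = -r:r, px = -r:r))
  rel_idx <- rel[, "py"] + rel[, "px"] * h
  base_idx <- (cy + offs$dy) + 1L + (cx + offs$dx) * h
  P <- matrix(frame[outer(base_idx, rel_idx, "+")], nrow = nrow(offs))

  tz <- as.numeric(template) - mean(template)
  tnorm <- sqrt(sum(tz^2))
  Pc <- P - rowMeans(P)
  pnorm <- sqrt(rowSums(Pc^2))
  score <- rep(0, nrow(offs))
  if (tnorm > 0) {
    ok <- pnorm > 0
    score[ok] <- (Pc[ok, , drop = FALSE] %*% tz) / (pnorm[ok] * tnorm)
  }
  list(offsets = offs, score = score, s = s)
}

#' Normalized cross-correlation match of a template in a search window
#'
#' Evaluates the zero-normalized cross-correlation of `template` against the
#' frame patch at every integer offset within the square window of half-width
#' `search_radius` around `center`, and returns the best offset and score.
#' Ties are broken by the smallest offset norm, then row-major order. Offsets
#' whose patch (or the template) has zero variance score 0.
#'
#' @param template Square grayscale matrix with odd side.
#' @param frame Grayscale frame matrix.
#' @param center Length-2 `c(x, y)` position (0-based px) to search around.
#' @param search_radius Half-width of the search window in px (>= 1).
#' @return List with `offset` (`c(dx, dy)`) and `score` (in [-1, 1]).
#' @export
ncc_match <- function(template, frame, center, search_radius) {
  sc <- ncc_scores(template, frame, center, search_radius)
  best <- max(sc$score)
  cand <- which(sc$score >= best - 1e-12)
  cand <- cand[order(sc$offsets$dx[cand]^2 + sc$offsets$dy[cand]^2)]
  i <- cand[1]
  list(offset = c(sc$offsets$dx[i], sc$offsets$dy[i]), score = sc$score[i])
}

# one-dimensional 3-point parabolic peak refinement, clamped to +/- 0.5
parabolic_refine <- function(sl, s0, sr) {
  den <- sl - 2 * s0 + sr
  if (den >= -1e-12) return(0)
  min(max(0.5 * (sl - sr) / den, -0.5), 0.5)
}

#' Track the catheter tip through a frame sequence
#'
#' Initializes a template at the seed point, then matches it frame to frame by
#' brute-force normalized cross-correlation within a local search window. The
#' integer-pixel match is refined to sub-pixel precision by fitting a parabola
#' through the score peak and its neighbours in each axis. By default the
#' template is refreshed from the newly found position after every frame
#' (tolerates a deforming catheter); `template_update = "fixed"` keeps the
#' seed template throughout, which is drift-free when the tip appearance is
#' constant. Frames whose best score falls below `score_threshold` are
#' reported as low-confidence; a `reseed` map can pin the position at those
#' frames, standing in for interactive correction.
#'
#' @param frames List of grayscale frame matrices (equal sizes).
#' @param seed_point `c(x, y)` tip position in the first frame (0-based px).
#' @param template_radius Template half-width in px (template side `2r+1`).
#' @param search_radius Search half-width in px.
#' @param score_threshold NCC score below which a frame is flagged.
#' @param dt Frame interval in s (timestamps are `frame * dt`).
#' @param template_update `"each_frame"` (refresh after every frame) or
#'   `"fixed"` (keep the seed template).
#' @param reseed Optional named list mapping 0-based frame index (as
#'   character) to a `c(x, y)` position that overrides the match there.
#' @return List with `trajectory` (data frame `frame`, `time_s`, `x_px`,
#'   `y_px`) and `flagged` (0-based indices of low-confidence frames).
#' @export
track_tip <- function(frames, seed_point, template_radius = 7,
                      search_radius = 15, score_threshold = 0.6,
                      dt = 1 / 25, template_update = c("each_frame", "fixed"),
                      reseed = NULL) {
  template_update <- match.arg(template_update)
  if (!length(frames)) stop_cathkin("no frames")
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  r <- as.integer(template_radius); s <- as.integer(search_radius)
  if (seed_point[1] < 0 || seed_point[1] > w - 1 ||
      seed_point[2] < 0 || seed_point[2] > h - 1)
    stop_cathkin("seed point outside the first frame")

  clamp <- function(p, margin) {
    c(min(max(p[1], margin), w - 1L - margin),
      min(max(p[2], margin), h - 1L - margin))
  }
  cut_template <- function(frame, p) {
    p <- round(clamp(p, r))
    frame[(p[2] - r):(p[2] + r) + 1L, (p[1] - r):(p[1] + r) + 1L]
  }

  n <- length(frames)
  x <- y <- numeric(n)
  flagged <- integer(0)
  pos <- c(seed_point[1], seed_point[2])
  x[1] <- pos[1]; y[1] <- pos[2]
  template <- cut_template(frames[[1]], pos)
  # sub-pixel location of the tracked point relative to the template center
  # (templates are cut at integer pixels, the seed need not be integral)
  phase <- pos - round(clamp(pos, r))

  for (i in seq_len(n)[-1]) {
    f <- frames[[i]]
    if (nrow(f) != h || ncol(f) != w)
      stop_cathkin(sprintf("frame %d changes size mid-sequence", i - 1L))
    center <- round(clamp(pos, r + s))
    sc <- ncc_scores(template, f, center, s)
    best <- max(sc$score)
    cand <- which(sc$score >= best - 1e-12)
    cand <- cand[order(sc$offsets$dx[cand]^2 + sc$offsets$dy[cand]^2)]
    k <- cand[1]
    dx <- sc$offsets$dx[k]; dy <- sc$offsets$dy[k]
    if (best < score_threshold) flagged <- c(flagged, i - 1L)

    # sub-pixel refinement from the score surface around the peak
    side <- 2L * s + 1L
    at <- function(ddx, ddy) sc$score[(ddy + s) * side + (ddx + s) + 1L]
    sub_x <- if (abs(dx) < s) parabolic_refine(at(dx - 1L, dy), best, at(dx + 1L, dy)) else 0
    sub_y <- if (abs(dy) < s) parabolic_refine(at(dx, dy - 1L), best, at(dx, dy + 1L)) else 0

    pos <- c(center[1] + dx + sub_x + phase[1], center[2] + dy + sub_y + phase[2])
    key <- as.character(i - 1L)
    if (!is.null(reseed) && !is.null(reseed[[key]]))
      pos <- c(reseed[[key]][1], reseed[[key]][2])
    x[i] <- pos[1]; y[i] <- pos[2]
    if (template_update == "each_frame") {
      template <- cut_template(f, pos)
      phase <- pos - round(clamp(pos, r))
    }
  }
  list(
    trajectory = data.frame(frame = seq_len(n) - 1L,
                            time_s = (seq_len(n) - 1L) * dt,
                            x_px = x, y_px = y),
    flagged = flagged
  )
}
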