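# Readers and writers for the artifact formats.
#
# Trajectories and feature tables are CSV (columns matched by name, any
# order); catheter shapes and stage annotations are JSON; images and masks are
# 8-bit grayscale PNG; distance images are 32-bit float TIFF storing px/1024
# (the canonical canvas diagonal is < 1024 px, and r-tiff stores only [0, 1]).
# All numeric fields round-trip at 1e-6 or better.

DIST_TIFF_SCALE <- 1024

#' @rdname trajectory_io
#' @export
write_trajectory_csv <- function(traj, path) {
  need <- c("frame", "time_s", "x_px", "y_px")
  miss <- setdiff(need, names(traj))
  if (length(miss)) stop_cathkin("missing columns: ", paste(miss, collapse = ", "))
  df <- traj[, need]
  df$time_s <- sprintf("%.9g", df$time_s)
  df$x_px <- sprintf("%.9g", df$x_px)
  df$y_px <- sprintf("%.9g", df$y_px)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trajectory CSV I/O
#'
#' Columns `frame`, `time_s`, `x_px`, `y_px`, matched by name in any order.
#' Malformed (non-numeric) entries are reported with their line number.
#'
#' @param traj Trajectory data frame.
#' @param path File path.
#' @return `read_trajectory_csv` returns the trajectory data frame.
#' @name trajectory_io
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "x_px", "y_px")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_cathkin("missing columns in ", path, ": ",
                                 paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop_cathkin("empty trajectory file: ", path)
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad))
      stop_cathkin(sprintf("malformed value in column %s at line %d of %s",
                           col, bad[1] + 1L, path))
    df[[col]] <- v
  }
  df$frame <- as.integer(df$frame)
  df[, need]
}

#' Catheter-shape JSON I/O
#'
#' Shapes are stored as `{"<frame>": [[x, y], ...], ...}` with a fixed number
#' of points per frame.
#'
#' @param shapes Named list of n x 2 matrices.
#' @param path File path.
#' @return `read_shapes_json` returns the named list of matrices.
#' @name shapes_io
#' @export
write_shapes_json <- function(shapes, path) {
  jsonlite::write_json(lapply(shapes, function(m) unname(as.matrix(m))),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname shapes_io
#' @export
read_shapes_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(m) matrix(as.numeric(m), ncol = 2))
}

#' Stage-annotation JSON I/O
#'
#' Stored as `{"stage1": [t0, t1], "stage2": [t0, t1]}` (seconds).
#'
#' @param stages List with `stage1`, `stage2` intervals.
#' @param path File path.
#' @return `read_stages_json` returns the stages list.
#' @name stages_io
#' @export
write_stages_json <- function(stages, path) {
  jsonlite::write_json(list(stage1 = stages$stage1, stage2 = stages$stage2),
                       path, digits = NA)
  invisible(path)
}

#' @rdname stages_io
#' @export
read_stages_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$stage1) || is.null(raw$stage2))
    stop_cathkin("stage JSON must contain stage1 and stage2: ", path)
  list(stage1 = as.numeric(raw$stage1), stage2 = as.numeric(raw$stage2))
}

#' Grayscale image / binary mask PNG I/O
#'
#' Images are 8-bit grayscale PNG (intensities 0..255); masks are written as
#' 0/255 and read back as logical.
#'
#' @param image Numeric matrix (0..255) or logical mask.
#' @param path File path.
#' @return Readers return the matrix (numeric for images, logical for masks).
#' @name image_io
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

#' @rdname image_io
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * 255
}

#' @rdname image_io
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' @rdname image_io
#' @export
read_mask_png <- function(path) {
  read_image_png(path) > 127.5
}

#' Distance-image TIFF I/O
#'
#' 32-bit float TIFF storing distance/1024 (round-trip error < 1e-4 px).
#'
#' @param dist Distance matrix (px).
#' @param path File path.
#' @return `read_distance_tiff` returns the `distance_image` matrix.
#' @name distance_io
#' @export
write_distance_tiff <- function(dist, path) {
  if (max(dist) >= DIST_TIFF_SCALE)
    stop_cathkin("distance values exceed the storable range")
  tiff::writeTIFF(unclass(dist) / DIST_TIFF_SCALE, path, bits.per.sample = 32L,
                  compression = "none")
  invisible(path)
}

#' @rdname distance_io
#' @export
read_distance_tiff <- function(path) {
  d <- tiff::readTIFF(path) * DIST_TIFF_SCALE
  structure(d, class = c("distance_image", "matrix", "array"))
}

#' Feature-table CSV I/O
#'
#' @param features Feature table (as from [cohort_features()]).
#' @param path File path.
#' @return `read_features_csv` returns the feature table.
#' @name features_io
#' @export
write_features_csv <- function(features, path) {
  df <- features
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.9g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname features_io
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_cathkin("empty features file: ", path)
  df
}

#' Write an analysis result list as JSON
#'
#' @param result Any list of numeric/character components (e.g. a
#'   `cluster_result` stripped of matrices).
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_results_json <- function(result, path) {
  jsonlite::write_json(result, path, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  invisible(path)
}
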