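# End-to-end pipeline: phantom -> segmentation -> cohort simulation ->
# kinematic features -> group statistics -> unsupervised discrimination.

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run with its default. One global
#' seed fixes all stochastic choices (simulator draws and clustering
#' restarts).
#'
#' @param n_expert,n_novice Subjects per group.
#' @param seed Global nonnegative integer seed.
#' @param scale Geometry/canvas scale (1 = 720 x 576).
#' @param dt Sampling interval in s.
#' @param noise_sd Phantom image noise sd (intensity units).
#' @param threshold Binarization threshold (0..255 or `"auto"`).
#' @param window,order Savitzky-Golay smoothing parameters.
#' @param between_subject_sd Between-subject parameter jitter (lognormal sd).
#' @param cluster_task,cluster_features,cluster_algorithm Discrimination
#'   settings (see [run_discrimination()]).
#' @param restarts k-means restarts.
#' @param profiles Group/equipment motion profiles.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_expert = 6, n_novice = 6, seed = 1,
                            scale = 1, dt = 1 / 25, noise_sd = 0,
                            threshold = "auto", window = 9, order = 3,
                            between_subject_sd = 0.15,
                            cluster_task = "experience",
                            cluster_features = c("T_p", "v_d", "a_d", "j_d"),
                            cluster_algorithm = "kmeans",
                            restarts = 100,
                            profiles = default_profiles()) {
  if (seed < 0 || seed != round(seed)) stop_cathkin("seed must be a nonnegative integer")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates the phantom and the cohort, segments the phantom (threshold
#' binarization + distance image), extracts per-stage kinematic features for
#' every execution, builds the median/p-value summary, and runs the
#' unsupervised discrimination. Fully deterministic under the config seed.
#' Each stage logs its parameters and row counts via `message()` when
#' `verbose` is on; logging never alters the numeric results.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, writes `features.csv`,
#'   `summary.csv`, `clustering.json`, `phantom.png`, `mask.png`,
#'   `distance.tif`.
#' @param verbose Log stage progress.
#' @return List with `features`, `summary`, `clustering`, `phantom`, `mask`,
#'   `dist`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[cathkin] ", sprintf(...))
  say("seed=%d, %d experts + %d novices, dt=%.4f s",
      config$seed, config$n_expert, config$n_novice, config$dt)

  geometry <- aorta_geometry(scale = config$scale)
  cs <- canvas_size(config$scale)
  ph <- with_seed(config$seed + 1L,
                  make_phantom(geometry, width = cs[1], height = cs[2],
                               noise_sd = config$noise_sd))
  say("phantom %d x %d, noise sd %.1f", cs[1], cs[2], config$noise_sd)

  mask <- binarize(ph$image, threshold = config$threshold,
                   largest_component = config$noise_sd > 0)
  dist <- distance_image(mask)
  say("segmentation: %d lumen px, max wall distance %.1f px",
      sum(mask), max(dist))

  cohort <- simulate_cohort(
    n_expert = config$n_expert, n_novice = config$n_novice,
    profiles = config$profiles, geometry = geometry, dt = config$dt,
    between_subject_sd = config$between_subject_sd, seed = config$seed)
  say("cohort: %d executions", nrow(cohort$subjects))

  features <- cohort_features(cohort, dist, dt = config$dt,
                              window = config$window, order = config$order)
  say("features: %d rows", nrow(features))

  summary <- summarize_cohort(features)
  clustering <- run_discrimination(
    features, task = config$cluster_task,
    feature_combo = config$cluster_features,
    algorithm = config$cluster_algorithm,
    seed = config$seed + 2L, restarts = config$restarts)
  say("discrimination (%s, %s): accuracy %d/%d", config$cluster_task,
      config$cluster_algorithm, clustering$n_correct, clustering$n)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_features_csv(features, file.path(out_dir, "features.csv"))
    write_features_csv(summary, file.path(out_dir, "summary.csv"))
    write_results_json(
      list(task = clustering$task, algorithm = clustering$method,
           features_used = clustering$features_used,
           assignments = clustering$assignments,
           objective = clustering$objective,
           accuracy = clustering$accuracy,
           n_correct = clustering$n_correct, n = clustering$n),
      file.path(out_dir, "clustering.json"))
    write_image_png(ph$image, file.path(out_dir, "phantom.png"))
    write_mask_png(mask, file.path(out_dir, "mask.png"))
    write_distance_tiff(dist, file.path(out_dir, "distance.tif"))
    say("wrote outputs to %s", out_dir)
  }
  list(features = features, summary = summary, clustering = clustering,
       phantom = ph$image, mask = mask, dist = dist, config = config)
}
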