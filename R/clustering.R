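# Unsupervised two-group discrimination from kinematic features.
#
# Two clustering routes: Lloyd k-means (within-cluster sum of squares, random
# restarts) and a two-component diagonal-covariance Gaussian mixture fitted by
# EM (initialized from the best k-means). With a dozen subjects and 2-4
# features, full covariances would be singular; diagonal components with a
# variance floor keep the likelihood bounded. Cluster labels are arbitrary, so
# accuracy against known labels is maximized over the two cluster-to-label
# bijections.

#' Standardize a feature matrix
#'
#' Centers each column to zero mean and scales to unit population standard
#' deviation (divisor n). Without this, features with large units (procedure
#' time, hundreds of s) would dominate the Euclidean metric.
#'
#' @param X Numeric matrix or data frame (>= 2 rows).
#' @return Standardized matrix with attributes `center` and `scale`.
#' @export
standardize <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop_cathkin("need at least 2 rows")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sdp <- sqrt(colMeans(Xc^2))
  zero <- which(sdp == 0)
  if (length(zero)) {
    nm <- colnames(X)[zero[1]]
    stop_cathkin("constant column: ", if (is.null(nm)) zero[1] else nm)
  }
  out <- sweep(Xc, 2, sdp, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- sdp
  out
}

#' Two-cluster k-means with random restarts
#'
#' Lloyd iterations from `restarts` random initializations (two distinct data
#' points as initial centers); the solution with the smallest within-cluster
#' sum of squares is kept. An emptied cluster is re-seeded at the point
#' farthest from the surviving center.
#'
#' @param X Numeric matrix (n >= 2 rows).
#' @param restarts Number of random initializations.
#' @param seed Integer seed (or `NULL` for the current RNG stream).
#' @param max_iter Lloyd iteration cap per restart.
#' @return Object of class `cluster_result`: `assignments` (1/2 per row),
#'   `centers` (2 x p), `objective` (SSE), `method = "kmeans"`.
#' @export
kmeans2 <- function(X, restarts = 100, seed = NULL, max_iter = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop_cathkin("need at least 2 points for k = 2")
  with_seed(seed, {
    best <- NULL
    for (rep in seq_len(restarts)) {
      repeat {
        centers <- X[sample.int(n, 2L), , drop = FALSE]
        if (any(centers[1, ] != centers[2, ])) break
        if (all(duplicated(X)[-1])) break  # all points identical
      }
      assign_old <- rep(0L, n)
      for (it in seq_len(max_iter)) {
        d1 <- rowSums(sweep(X, 2, centers[1, ])^2)
        d2 <- rowSums(sweep(X, 2, centers[2, ])^2)
        asg <- ifelse(d1 <= d2, 1L, 2L)
        for (k in 1:2) {
          if (!any(asg == k)) {
            far <- which.max(rowSums(sweep(X, 2, centers[3 - k, ])^2))
            centers[k, ] <- X[far, ]
            asg[far] <- k
          }
        }
        if (identical(asg, assign_old)) break
        assign_old <- asg
        centers[1, ] <- colMeans(X[asg == 1L, , drop = FALSE])
        centers[2, ] <- colMeans(X[asg == 2L, , drop = FALSE])
      }
      sse <- sum((X - centers[asg, , drop = FALSE])^2)
      if (is.null(best) || sse < best$objective - 1e-12) {
        best <- list(assignments = asg, centers = centers, objective = sse,
                     method = "kmeans")
      }
    }
    structure(best, class = "cluster_result")
  })
}

#' Two-component diagonal Gaussian mixture via EM
#'
#' Fits a 2-component Gaussian mixture with diagonal covariances by
#' expectation-maximization, initialized from the best k-means partition.
#' Component variances are floored at `1e-4` of the column variance so no
#' component can collapse onto a point. Iterates until the log-likelihood gain
#' drops below `tol`; the log-likelihood is non-decreasing by construction and
#' the full trace is returned. Points are assigned by maximum responsibility.
#' For plotting, the 70% confidence ellipse of each component is reported as
#' per-axis radii \eqn{\sqrt{q_{\chi^2_2}(0.7)} \sigma}.
#'
#' @param X Numeric matrix (n >= 4 rows).
#' @param seed Integer seed for the k-means initialization.
#' @param max_iter EM iteration cap.
#' @param tol Log-likelihood convergence tolerance.
#' @param restarts Restarts for the initializing k-means.
#' @return Object of class `cluster_result`: `assignments`, `means` (2 x p),
#'   `variances` (2 x p), `weights`, `responsibilities` (n x 2), `objective`
#'   (final log-likelihood), `loglik_trace`, `ellipse70`, `method = "em"`.
#' @export
em_gmm2 <- function(X, seed = NULL, max_iter = 200, tol = 1e-8, restarts = 20) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 4L) stop_cathkin("need at least 4 points for a 2-component mixture")
  km <- kmeans2(X, restarts = restarts, seed = seed)
  colvar <- apply(X, 2, stats::var)
  floorv <- pmax(1e-4 * colvar, 1e-12)

  mu <- km$centers
  sig2 <- rbind(colvar, colvar)
  for (k in 1:2) {
    xs <- X[km$assignments == k, , drop = FALSE]
    if (nrow(xs) >= 2L) sig2[k, ] <- apply(xs, 2, stats::var)
  }
  sig2 <- pmax(sig2, rep(floorv, each = 2))
  wgt <- tabulate(km$assignments, 2L) / n

  log_dens <- function() {
    ld <- matrix(0, n, 2)
    for (k in 1:2) {
      ld[, k] <- log(wgt[k]) - 0.5 * sum(log(2 * pi * sig2[k, ])) -
        0.5 * rowSums(sweep(sweep(X, 2, mu[k, ])^2, 2, sig2[k, ], "/"))
    }
    ld
  }
  trace <- numeric(0)
  resp <- NULL
  for (it in seq_len(max_iter)) {
    ld <- log_dens()
    m <- pmax(ld[, 1], ld[, 2])
    ll <- sum(m + log(exp(ld[, 1] - m) + exp(ld[, 2] - m)))
    trace <- c(trace, ll)
    if (it > 1L && ll - trace[it - 1L] < tol) break
    resp <- exp(ld - (m + log(exp(ld[, 1] - m) + exp(ld[, 2] - m))))
    nk <- colSums(resp)
    if (any(nk < 1e-8)) stop_cathkin("mixture component collapsed")
    wgt <- nk / n
    for (k in 1:2) {
      mu[k, ] <- colSums(resp[, k] * X) / nk[k]
      sig2[k, ] <- pmax(colSums(resp[, k] * sweep(X, 2, mu[k, ])^2) / nk[k], floorv)
    }
  }
  r70 <- sqrt(stats::qchisq(0.7, df = 2))
  structure(list(
    assignments = ifelse(resp[, 1] >= resp[, 2], 1L, 2L),
    means = mu, variances = sig2, weights = wgt,
    responsibilities = resp,
    objective = trace[length(trace)], loglik_trace = trace,
    ellipse70 = lapply(1:2, function(k)
      list(center = mu[k, ], radii = r70 * sqrt(sig2[k, ]))),
    method = "em"
  ), class = "cluster_result")
}

#' Clustering accuracy against known labels
#'
#' Cluster indices are arbitrary, so accuracy is the best match fraction over
#' the two possible cluster-to-label bijections.
#'
#' @param assignments Integer cluster indices (values in 1..2).
#' @param labels True labels (exactly 2 distinct values).
#' @return List `accuracy` (fraction), `n_correct`, `n`.
#' @export
clustering_accuracy <- function(assignments, labels) {
  if (length(assignments) != length(labels)) stop_cathkin("length mismatch")
  lv <- unique(labels)
  if (length(lv) > 2L) stop_cathkin("more than 2 distinct labels")
  n <- length(labels)
  m1 <- sum((assignments == 1L) == (labels == lv[1]))
  n_correct <- max(m1, n - m1)
  list(accuracy = n_correct / n, n_correct = n_correct, n = n)
}

#' Unsupervised discrimination of experience level or equipment
#'
#' Selects the stage-1 features of the requested subset, standardizes them,
#' clusters with k = 2, and scores the partition against the true labels. The
#' experience task uses one execution per subject (one equipment condition,
#' conventional by default); the equipment task uses both executions of one
#' experience group (experts by default) with the `{T_p, a_d}` default subset.
#'
#' @param features Feature table as from [cohort_features()].
#' @param task `"experience"` or `"equipment"`.
#' @param feature_combo Feature column names; defaults are
#'   `c("T_p","v_d","a_d","j_d")` for experience and `c("T_p","a_d")` for
#'   equipment.
#' @param algorithm `"kmeans"` or `"em"`.
#' @param seed Integer seed.
#' @param equipment Equipment condition used for the experience task.
#' @param group Experience group used for the equipment task.
#' @param restarts k-means restarts.
#' @return The `cluster_result` with added `accuracy`, `n_correct`, `n`,
#'   `labels`, `task`, `features_used`.
#' @export
run_discrimination <- function(features, task = c("experience", "equipment"),
                               feature_combo = NULL,
                               algorithm = c("kmeans", "em"), seed = NULL,
                               equipment = "conventional", group = "expert",
                               restarts = 100) {
  task <- match.arg(task)
  algorithm <- match.arg(algorithm)
  if (is.null(feature_combo))
    feature_combo <- if (task == "experience") c("T_p", "v_d", "a_d", "j_d")
                     else c("T_p", "a_d")
  allowed <- c("T_p", "PL", "v_d", "a_d", "j_d", "d_tip", "d_shape")
  bad <- setdiff(feature_combo, allowed)
  if (length(bad)) stop_cathkin("unknown feature name: ", paste(bad, collapse = ", "))
  if (!all(feature_combo %in% names(features)))
    stop_cathkin("feature columns missing from the table")

  if (task == "experience") {
    rows <- features$stage == 1 & features$equipment == equipment
    labels <- features$group[rows]
  } else {
    rows <- features$stage == 1 & features$group == group
    labels <- features$equipment[rows]
  }
  X <- standardize(as.matrix(features[rows, feature_combo, drop = FALSE]))
  res <- if (algorithm == "kmeans") kmeans2(X, restarts = restarts, seed = seed)
         else em_gmm2(X, seed = seed, restarts = restarts)
  acc <- clustering_accuracy(res$assignments, labels)
  res$accuracy <- acc$accuracy
  res$n_correct <- acc$n_correct
  res$n <- acc$n
  res$labels <- labels
  res$task <- task
  res$features_used <- feature_combo
  res
}
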