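# Two-group clustering and accuracy scoring.

test_that("standardization centers, scales and round-trips", {
  X <- cbind(a = c(0, 10, 5, 5), b = c(-1, 1, 0, 0))
  Z <- standardize(X)
  expect_equal(colMeans(Z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(sqrt(colMeans(Z^2)), c(a = 1, b = 1), tolerance = 1e-12)
  # population sd: column {0, 10} -> {-1, 1}
  expect_equal(standardize(cbind(v = c(0, 10)))[, "v"], c(-1, 1))
  # destandardize via the attributes
  back <- sweep(sweep(Z, 2, attr(Z, "scale"), "*"), 2, attr(Z, "center"), "+")
  expect_equal(unname(back), unname(X), tolerance = 1e-12, ignore_attr = TRUE)
  # already standardized input is unchanged
  expect_equal(unname(standardize(Z)), unname(Z), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(standardize(cbind(u = c(1, 1, 1), v = 1:3)), "constant column: u")
})

test_that("k-means solves the tiny and well-separated cases", {
  X <- rbind(c(0, 0), c(5, 5))
  km <- kmeans2(X, restarts = 5, seed = 1)
  expect_equal(km$objective, 0)
  expect_equal(sort(unique(km$assignments)), c(1L, 2L))

  set.seed(61)
  X2 <- rbind(matrix(rnorm(20, 0, 0.2), 10, 2),
              matrix(rnorm(20, 10, 0.2), 10, 2))
  km2 <- kmeans2(X2, restarts = 20, seed = 2)
  expect_equal(clustering_accuracy(km2$assignments,
                                   rep(1:2, each = 10))$accuracy, 1)
  expect_error(kmeans2(X[1, , drop = FALSE]), "at least 2")
  # determinism under seed
  expect_identical(kmeans2(X2, restarts = 10, seed = 3),
                   kmeans2(X2, restarts = 10, seed = 3))
})

test_that("k-means with restarts attains the exhaustive-bipartition optimum", {
  set.seed(62)
  hits <- 0
  for (i in 1:12) {
    X <- matrix(rnorm(24), 12, 2)
    km <- kmeans2(X, restarts = 100, seed = i)
    if (abs(km$objective - oracle_min_sse(X)) < 1e-8) hits <- hits + 1
  }
  expect_gte(hits, 11)
})

test_that("EM recovers separated components and never decreases the likelihood", {
  set.seed(63)
  X <- rbind(matrix(rnorm(60, 0, 0.3), 30, 2),
             matrix(rnorm(60, 6, 0.3), 30, 2))
  em <- em_gmm2(X, seed = 4)
  mu <- em$means[order(em$means[, 1]), ]
  expect_lt(max(abs(mu[1, ] - c(0, 0))), 0.2)
  expect_lt(max(abs(mu[2, ] - c(6, 6))), 0.2)
  expect_true(all(diff(em$loglik_trace) > -1e-8))
  expect_equal(sum(em$weights), 1, tolerance = 1e-12)
  # responsibilities are saturated on well-separated data
  expect_true(all(pmax(em$responsibilities[, 1],
                       em$responsibilities[, 2]) > 0.999))
  expect_error(em_gmm2(X[1:3, ]), "at least 4")

  # monotone log-likelihood on unstructured data too
  for (i in 1:10) {
    Xr <- matrix(rnorm(30), 15, 2)
    emr <- em_gmm2(Xr, seed = i)
    expect_true(all(diff(emr$loglik_trace) > -1e-8))
  }
})

test_that("EM agrees with an independent mixture fit on separated data", {
  suppressMessages(library(mclust))
  set.seed(64)
  X <- rbind(matrix(rnorm(100, 0, 0.5), 50, 2),
             matrix(rnorm(100, 5, 0.5), 50, 2))
  em <- em_gmm2(X, seed = 5)
  mc <- Mclust(X, G = 2, modelNames = "VVI", verbose = FALSE)
  mu_pkg <- em$means[order(em$means[, 1]), ]
  mu_ref <- t(mc$parameters$mean)[order(t(mc$parameters$mean)[, 1]), ]
  expect_equal(unname(mu_pkg), unname(mu_ref), tolerance = 0.05)
})

test_that("accuracy is label-permutation invariant and floors at one half", {
  lab <- rep(c("a", "b"), each = 6)
  asg <- c(rep(2L, 6), rep(1L, 6))  # perfectly anti-aligned
  expect_equal(clustering_accuracy(asg, lab)$accuracy, 1)
  expect_equal(clustering_accuracy(asg, lab)$n_correct, 12)

  set.seed(65)
  for (i in 1:20) {
    r <- sample(1:2, 12, replace = TRUE)
    expect_gte(clustering_accuracy(r, lab)$accuracy, 0.5)
  }
  expect_error(clustering_accuracy(rep(1L, 4), c("x", "y", "z", "w")),
               "more than 2")
})

test_that("experience discrimination separates the default synthetic groups", {
  g <- aorta_geometry()
  cs <- canvas_size(1)
  dist <- distance_image(make_phantom(g, width = cs[1], height = cs[2])$mask)
  accs <- vapply(1:5, function(i) {
    co <- simulate_cohort(geometry = g, seed = i)
    f <- cohort_features(co, dist)
    run_discrimination(f, "experience", seed = 100 + i)$n_correct
  }, numeric(1))
  expect_gte(median(accs), 10)  # >= 10/12 subjects

  co <- simulate_cohort(geometry = g, seed = 3)
  f <- cohort_features(co, dist)
  r1 <- run_discrimination(f, "experience", algorithm = "em", seed = 9)
  r2 <- run_discrimination(f, "experience", algorithm = "em", seed = 9)
  expect_identical(r1$assignments, r2$assignments)
  expect_error(run_discrimination(f, "experience", feature_combo = "bogus"),
               "unknown feature")
  # equipment task runs on the expert pairs
  re <- run_discrimination(f, "equipment", seed = 11)
  expect_equal(re$n, 12)  # 6 experts x 2 equipment
  expect_gte(re$accuracy, 0.5)

  # one subject per group: too few points for a 2-component mixture
  tiny <- data.frame(subject_id = c("S1", "S2"), group = c("expert", "novice"),
                     equipment = "conventional", stage = 1,
                     T_p = c(5, 30), v_d = c(20, 8), a_d = c(60, 50),
                     j_d = c(400, 9000))
  expect_error(run_discrimination(tiny, "experience", algorithm = "em",
                                  seed = 1), "at least 4")
})
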