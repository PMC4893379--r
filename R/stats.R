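# Exact small-sample nonparametric group comparisons.
#
# With 6 subjects per group, the normal approximation to the rank-test null
# distributions is poor; both tests here enumerate the exact permutation null
# (all group assignments for Mann-Whitney, all sign patterns for the Wilcoxon
# signed-rank test), using mid-ranks for ties. Two-sided p is twice the
# smaller tail probability, capped at 1. The attainable floor for n = 6 pairs
# is 2/64 = 0.03125.

#' Exact Mann-Whitney U test
#'
#' U statistic of the first sample (with 0.5 credit for ties) and an exact
#' two-sided p-value from full enumeration of all `choose(n1+n2, n1)` group
#' assignments of the pooled values.
#'
#' @param a,b Numeric samples (each non-empty; intended for <= 10 per group).
#' @return List of class `cathkin_test` with `method`, `statistic` (U of `a`),
#'   `p.value`, `n` (`c(n1, n2)`).
#' @export
mann_whitney_exact <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop_cathkin("both samples must be non-empty")
  if (n1 + n2 > 22L)
    stop_cathkin("exact enumeration limited to n1 + n2 <= 22")
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  p <- min(1, 2 * min(mean(Us <= U_obs + eps), mean(Us >= U_obs - eps)))
  structure(list(method = "exact Mann-Whitney U", statistic = U_obs,
                 p.value = p, n = c(n1 = n1, n2 = n2)),
            class = "cathkin_test")
}

#' Exact Wilcoxon signed-rank test
#'
#' Drops zero differences, ranks |d| with mid-ranks for ties, and computes the
#' exact two-sided p-value by enumerating all 2^n sign patterns.
#'
#' @param x,y Paired numeric samples of equal length (intended n <= 15).
#' @return List of class `cathkin_test` with `method`, `statistic` (W+, the
#'   positive-rank sum), `p.value`, `n` (pairs used after dropping zeros).
#' @export
wilcoxon_signed_rank_exact <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_cathkin("paired samples must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop_cathkin("all differences are zero: no information")
  if (n > 16L) stop_cathkin("exact enumeration limited to n <= 16 non-zero pairs")
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  eps <- 1e-9
  p <- min(1, 2 * min(mean(Ws <= W_obs + eps), mean(Ws >= W_obs - eps)))
  structure(list(method = "exact Wilcoxon signed-rank", statistic = W_obs,
                 p.value = p, n = c(pairs = n)),
            class = "cathkin_test")
}

#' @export
print.cathkin_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic),
      " p =", format(x$p.value), " n =", paste(x$n, collapse = ", "), "\n")
  invisible(x)
}

#' Median/p-value summary of a cohort feature table
#'
#' Builds the standard summary of a two-group, two-equipment, two-stage
#' feature table: per feature and stage, group medians per equipment, exact
#' Mann-Whitney p across experience groups per equipment, and exact Wilcoxon
#' signed-rank p across equipment per experience group (pairing executions by
#' subject).
#'
#' @param features Feature table as from [cohort_features()] (columns
#'   `subject_id`, `group` in novice/expert, `equipment` in
#'   conventional/robotic, `stage`, and the feature columns).
#' @param feature_cols Feature columns to summarize.
#' @param alpha Significance level used for the `sig_*` marker columns.
#' @return Data frame with one row per feature x stage.
#' @export
summarize_cohort <- function(features,
                             feature_cols = c("T_p", "v_d", "a_d", "j_d",
                                              "d_tip", "d_shape"),
                             alpha = 0.05) {
  need <- c("subject_id", "group", "equipment", "stage", feature_cols)
  miss <- setdiff(need, names(features))
  if (length(miss)) stop_cathkin("missing columns: ", paste(miss, collapse = ", "))
  cells <- expand.grid(group = c("novice", "expert"),
                       equipment = c("conventional", "robotic"),
                       stage = 1:2, stringsAsFactors = FALSE)
  have <- unique(features[, c("group", "equipment", "stage")])
  missing_cells <- !apply(cells, 1, function(r)
    any(have$group == r["group"] & have$equipment == r["equipment"] &
        have$stage == as.numeric(r["stage"])))
  if (any(missing_cells))
    stop_cathkin("missing cohort cells: ",
                 paste(apply(cells[missing_cells, ], 1, paste, collapse = "/"),
                       collapse = "; "))

  pick <- function(grp, eqp, stg, col) {
    rows <- features$group == grp & features$equipment == eqp & features$stage == stg
    v <- features[rows, ]
    v <- v[order(v$subject_id), ]
    v[[col]]
  }
  out <- list()
  for (col in feature_cols) for (stg in 1:2) {
    nov_c <- pick("novice", "conventional", stg, col)
    exp_c <- pick("expert", "conventional", stg, col)
    nov_r <- pick("novice", "robotic", stg, col)
    exp_r <- pick("expert", "robotic", stg, col)
    p_mw_c <- mann_whitney_exact(nov_c, exp_c)$p.value
    p_mw_r <- mann_whitney_exact(nov_r, exp_r)$p.value
    p_wi_n <- wilcoxon_signed_rank_exact(nov_c, nov_r)$p.value
    p_wi_e <- wilcoxon_signed_rank_exact(exp_c, exp_r)$p.value
    out[[length(out) + 1L]] <- data.frame(
      feature = col, stage = stg,
      median_novice_conventional = stats::median(nov_c),
      median_expert_conventional = stats::median(exp_c),
      p_mw_conventional = p_mw_c,
      median_novice_robotic = stats::median(nov_r),
      median_expert_robotic = stats::median(exp_r),
      p_mw_robotic = p_mw_r,
      p_wi_novice = p_wi_n, p_wi_expert = p_wi_e,
      sig_mw_conventional = p_mw_c < alpha,
      sig_mw_robotic = p_mw_r < alpha,
      sig_wi_novice = p_wi_n < alpha,
      sig_wi_expert = p_wi_e < alpha
    )
  }
  do.call(rbind, out)
}
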