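#' Expected number of nominally significant tests under the global null
#'
#' With `n_features` independent true nulls, an average of
#' `alpha * n_features` tests fall below `alpha` by chance; at
#' `alpha = 0.05` over 22,366 connectivities that is 1,118 -- the scale of
#' the multiple-comparisons problem the second-level HC test addresses.
#'
#' @param n_features Number of tests.
#' @param alpha Per-test significance level in `[0, 1]`.
#' @return List with `expected` (exact, `alpha * n_features`) and `count`
#'   (rounded to the nearest integer).
#' @examples
#' expected_null_significant(22366, 0.05)
#' @export
expected_null_significant <- function(n_features, alpha) {
  n_features <- assert_count(n_features, "n_features")
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stopf("`alpha` must be a single value in [0, 1]")
  }
  expected <- alpha * n_features
  list(expected = expected, count = as.integer(round(expected)))
}

# One pass of the rare/weak power simulation, evaluated at every n in
# n_grid with common random numbers: each simulation draws its noise once
# at max(n_grid) and every grid point uses the leading rows, so power
# estimates across n share Monte Carlo noise (variance reduction for
# monotonicity and minimal-n comparisons).
power_sim_grid <- function(n_grid, n_features, k_nonnull, effect, threshold,
                           n_sims, seed) {
  if (any(n_grid <= 3)) stopf("sample sizes must exceed 3 (t statistic needs df >= 1)")
  if (abs(effect) >= 1) stopf("`effect` is a correlation and must satisfy |effect| < 1")
  if (k_nonnull > n_features) stopf("k_nonnull cannot exceed n_features")
  n_sims <- assert_count(n_sims, "n_sims", min = 1L)
  n_max <- max(n_grid)
  rej <- matrix(FALSE, n_sims, length(n_grid))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(assert_seed(seed))
  for (s in seq_len(n_sims)) {
    w_full <- rnorm(n_max)
    Y_full <- matrix(rnorm(n_max * n_features), n_max, n_features)
    if (k_nonnull > 0 && effect != 0) {
      Y_full[, seq_len(k_nonnull)] <- effect * w_full +
        sqrt(1 - effect^2) * Y_full[, seq_len(k_nonnull)]
    }
    for (g in seq_along(n_grid)) {
      n <- n_grid[g]
      w <- w_full[seq_len(n)]
      Y <- Y_full[seq_len(n), , drop = FALSE]
      wc <- w - mean(w)
      num <- as.vector(crossprod(wc, Y)) # sum(wc) = 0, so this is the centered cross-product
      den <- sqrt(sum(wc^2)) * sqrt(colSums(Y^2) - n * colMeans(Y)^2)
      r <- num / den
      tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
      p <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
      curve <- suppressWarnings(hc_curve(p))
      rej[s, g] <- curve$hc_max > threshold
    }
  }
  power <- colMeans(rej)
  data.frame(n = n_grid, power = power,
             se = sqrt(power * (1 - power) / n_sims))
}

#' Monte Carlo power of the max-HC detection rule
#'
#' Simulates the design-stage rare/weak scenario: a standardized worry
#' vector, `n_features` unit-variance Gaussian edge outcomes of which
#' `k_nonnull` have population correlation `effect` with worry, per-feature
#' two-sided p-values from the simple-regression t statistic, and the
#' global decision `max HC > threshold`. Power is the rejection fraction.
#' With `effect = 0` (or `k_nonnull = 0`) the estimate is the rule's null
#' rejection rate, which for the plain full-range statistic at threshold 2
#' is far above the nominal 5% at realistic `n_features` -- report it, do
#' not assume it.
#'
#' @param n_subjects Sample size (> 3).
#' @param n_features Number of edge-level tests (default 22,366).
#' @param k_nonnull Number of non-null features (default 100).
#' @param effect Population worry-feature correlation of non-null features
#'   (equivalently the standardized simple-regression slope; default 0.1).
#' @param threshold Max-HC decision threshold (default 2).
#' @param n_sims Number of simulations (default 200).
#' @param seed Integer seed; identical seeds give identical estimates.
#' @return List with `power`, `se` (binomial Monte Carlo standard error),
#'   and the scenario parameters.
#' @export
simulate_power <- function(n_subjects, n_features = 22366L, k_nonnull = 100L,
                           effect = 0.1, threshold = 2, n_sims = 200L,
                           seed = 1L) {
  tab <- power_sim_grid(assert_count(n_subjects, "n_subjects", min = 4L),
                        assert_count(n_features, "n_features", min = 2L),
                        assert_count(k_nonnull, "k_nonnull"),
                        effect, threshold, n_sims, seed)
  list(power = tab$power[1L], se = tab$se[1L], n_subjects = tab$n[1L],
       n_features = n_features, k_nonnull = k_nonnull, effect = effect,
       threshold = threshold, n_sims = n_sims, seed = seed)
}

#' Smallest sample size reaching a target power
#'
#' Estimates power at every candidate `n` with common random numbers (the
#' same simulated cohorts, truncated to each `n`) and returns the smallest
#' grid value whose estimated power reaches `target_power`. When no grid
#' point reaches the target and `extend = TRUE`, the grid is extended
#' upward in steps of `extend_step` until the target is reached or
#' `extend_max` is hit, so the returned minimal n is always a measured
#' quantity.
#'
#' @param n_grid Ascending candidate sample sizes.
#' @param target_power Target power in `(0, 1)` (default 0.8).
#' @param extend Extend the grid upward when the target is not reached on
#'   `n_grid` (default `FALSE`).
#' @param extend_step,extend_max Extension step and cap.
#' @inheritParams simulate_power
#' @return List with `n_min` (`NA` when the target was not reached),
#'   `reached`, `target_power`, and `table` (power vs n, with Monte Carlo
#'   SEs).
#' @export
minimal_n_for_power <- function(n_grid, target_power = 0.8,
                                n_features = 22366L, k_nonnull = 100L,
                                effect = 0.1, threshold = 2, n_sims = 200L,
                                seed = 1L, extend = FALSE, extend_step = 40L,
                                extend_max = 401L) {
  if (is.unsorted(n_grid, strictly = TRUE)) stopf("`n_grid` must be strictly ascending")
  if (target_power <= 0 || target_power >= 1) stopf("`target_power` must be in (0, 1)")
  tab <- power_sim_grid(as.integer(n_grid), n_features, k_nonnull, effect,
                        threshold, n_sims, seed)
  while (extend && !any(tab$power >= target_power) &&
         max(tab$n) + extend_step <= extend_max) {
    more <- power_sim_grid(max(tab$n) + extend_step, n_features, k_nonnull,
                           effect, threshold, n_sims, seed)
    tab <- rbind(tab, more)
  }
  hit <- which(tab$power >= target_power)
  list(
    n_min = if (length(hit)) tab$n[min(hit)] else NA_integer_,
    reached = length(hit) > 0,
    target_power = target_power,
    table = tab
  )
}
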