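#' Bootstrap prevalence tally of HC-selected edges
#'
#' Subject-resampling bootstrap of the whole second-level analysis. Per
#' iteration: resample `n` subjects with replacement, rebuild the design
#' matrix (categorical levels may collapse; rank-breaking resamples are
#' redrawn and counted), refit all edges, compute the HC curve. If the
#' maximum HC statistic is below `threshold`, nothing is tallied;
#' otherwise every edge in the max-HC selected set has its tally
#' incremented. The resulting prevalence ranks edge importance -- it is
#' explicitly *not* a significance test (weak effects are not expected to
#' be re-selected in 95\% of iterations).
#'
#' Note the tally rule uses `max HC >= threshold` (the complement of the
#' "less than `threshold` means nothing is tallied" rule), which differs
#' from the strict `>` of the global decision; both are configurable.
#'
#' @param subjects A complete-case `subject_table`.
#' @param panel The matching [connectivity_panel()].
#' @param B Number of bootstrap iterations (default 1000).
#' @param threshold Tally threshold on the max HC statistic (default 2).
#' @param seed Master seed; one child seed per iteration is pre-drawn, so
#'   the tally is reproducible and iteration order is immaterial.
#' @param madrs_threshold Passed to the per-resample design build.
#' @param max_redraw_frac Abort when redraws exceed this fraction of `B`
#'   (degenerate design; default 0.5).
#' @return A data frame of class `tally_table` with columns
#'   `edge_id, tally, prevalence` (`prevalence = tally / B`), and
#'   attributes `B`, `B_informative` (iterations that tallied), `threshold`,
#'   `seed`, `redraws`, `max_selected_size`, `is_significance_test = FALSE`.
#' @export
bootstrap_tally <- function(subjects, panel, B = 1000L, threshold = 2,
                            seed = 1L, madrs_threshold = 14,
                            max_redraw_frac = 0.5) {
  B <- assert_count(B, "B")
  stopifnot(inherits(panel, "connectivity_panel"))
  if (nrow(subjects) != nrow(panel$z) ||
      !identical(as.character(subjects$subject_id), panel$subject_id)) {
    stopf("subjects and panel are not aligned by subject id")
  }
  n <- nrow(subjects)
  E <- ncol(panel$z)
  tally <- integer(E)
  B_informative <- 0L
  redraws <- 0L
  max_sel <- 0L
  iter_seeds <- derive_seeds(seed, B)

  for (b in seq_len(B)) {
    old <- get_rng_state()
    set.seed(iter_seeds[b])
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      design <- tryCatch(
        build_design_matrix(subjects[idx, , drop = FALSE], madrs_threshold = madrs_threshold),
        error = function(e) NULL
      )
      if (!is.null(design)) break
      redraws <- redraws + 1L
      if (redraws > max_redraw_frac * B) {
        restore_rng_state(old)
        stopf("bootstrap aborted: %d redraws exceeded %.0f%% of B = %d (degenerate design)",
              redraws, 100 * max_redraw_frac, B)
      }
    }
    restore_rng_state(old)
    res <- fit_edge_regressions(panel$z[idx, , drop = FALSE], design)
    curve <- suppressWarnings(hc_curve(res$p))
    if (curve$hc_max >= threshold) {
      sel_idx <- curve$order[seq_len(curve$i_star)]
      tally[sel_idx] <- tally[sel_idx] + 1L
      B_informative <- B_informative + 1L
      max_sel <- max(max_sel, curve$i_star)
    }
  }

  out <- data.frame(edge_id = 0:(E - 1L), tally = tally,
                    prevalence = if (B > 0) tally / B else rep(0, E))
  attr(out, "B") <- B
  attr(out, "B_informative") <- B_informative
  attr(out, "threshold") <- threshold
  attr(out, "seed") <- seed
  attr(out, "redraws") <- redraws
  attr(out, "max_selected_size") <- max_sel
  attr(out, "is_significance_test") <- FALSE
  class(out) <- c("tally_table", class(out))
  out
}

#' Rank edges by bootstrap prevalence
#'
#' Descending tally; ties broken by ascending full-sample p-value, then by
#' edge id. When every tally is zero the ranking therefore reduces to the
#' full-sample p-value ordering.
#'
#' @param tally A [bootstrap_tally()] result.
#' @param results The matching full-sample `edge_regression_results`.
#' @return Data frame with columns
#'   `rank, edge_id, tally, prevalence, p, beta`, one row per edge.
#' @export
rank_edges <- function(tally, results) {
  if (!identical(tally$edge_id, results$edge_id)) {
    stopf("tally and results edge ids are misaligned")
  }
  ord <- order(-tally$tally, results$p, tally$edge_id, method = "radix")
  out <- data.frame(
    rank = seq_along(ord),
    edge_id = tally$edge_id[ord],
    tally = tally$tally[ord],
    prevalence = tally$prevalence[ord],
    p = results$p[ord],
    beta = results$beta[ord],
    row.names = NULL
  )
  attr(out, "is_significance_test") <- FALSE
  out
}
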