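#' Higher criticism curve over a set of p-values
#'
#' Arranges the p-values in ascending order and compares the empirical
#' distribution to the uniform null at every rank:
#' \deqn{HC_i = \sqrt{n}\,\frac{i/n - p_{(i)}}{\sqrt{(i/n)(1 - i/n)}},
#'   \quad i = 1, \dots, n-1.}
#' Each \eqn{HC_i} is a z-score-like quantity (binomial mean \eqn{i/n},
#' variance \eqn{(i/n)(1-i/n)/n}); the rank \eqn{i = n} is excluded because
#' its binomial variance is zero. The maximum over ranks is the global
#' test statistic and its argmax defines the selection cutoff.
#'
#' Ties in `p` keep input order (stable sort); a tied maximum resolves to
#' the smallest rank. p-values of exactly 0 (upstream underflow) are
#' floored at `1e-300` with a warning.
#'
#' @param p Numeric vector of p-values in `(0, 1]`, length >= 2.
#' @param alpha0 Optional restriction of the evaluated range to ranks with
#'   `i/n <= alpha0` (default 1: the full range).
#' @param plus If `TRUE`, ranks with `p_(i) < 1/n` are excluded from the
#'   maximum (the "HC+" stabilization). Off by default.
#' @return An object of class `hc_curve`: list with `n_tests`, `sorted_p`,
#'   `order` (permutation from rank back to input position), `hc` (length
#'   `n - 1`), `eligible` (logical, which ranks compete for the maximum),
#'   `hc_max`, `i_star`, `alpha0`, `plus`.
#' @examples
#' hc_curve(c(0.01, 0.20, 0.50, 0.90))
#' @export
hc_curve <- function(p, alpha0 = 1, plus = FALSE) {
  if (!is.numeric(p)) stopf("`p` must be numeric")
  if (any(is.na(p))) stopf("`p` contains NA/NaN")
  n <- length(p)
  if (n < 2L) stopf("at least 2 p-values are required")
  if (any(p < 0 | p > 1)) stopf("p-values must lie in (0, 1]")
  if (any(p == 0)) {
    warnf("hc_curve: %d p-value(s) of exactly 0 floored at 1e-300 (upstream underflow?)",
          sum(p == 0))
    p[p == 0] <- 1e-300
  }
  if (alpha0 <= 0 || alpha0 > 1) stopf("`alpha0` must be in (0, 1]")

  ord <- order(p, method = "radix") # stable: ties keep input order
  ps <- p[ord]
  i <- seq_len(n - 1L)
  frac <- i / n
  hc <- sqrt(n) * (frac - ps[i]) / sqrt(frac * (1 - frac))

  eligible <- rep(TRUE, n - 1L)
  if (alpha0 < 1) eligible <- eligible & (frac <= alpha0)
  if (plus) eligible <- eligible & (ps[i] >= 1 / n)
  if (!any(eligible)) stopf("no rank is eligible under alpha0 = %g, plus = %s", alpha0, plus)

  hc_eval <- ifelse(eligible, hc, -Inf)
  hc_max <- max(hc_eval)
  i_star <- which(hc_eval == hc_max)[1L] # smallest tied rank

  structure(list(n_tests = n, sorted_p = ps, order = ord, hc = hc,
                 eligible = eligible, hc_max = hc_max, i_star = i_star,
                 alpha0 = alpha0, plus = plus),
            class = "hc_curve")
}

#' @export
print.hc_curve <- function(x, ...) {
  cat(sprintf("hc_curve: n = %d tests, max HC = %.4f at rank %d\n",
              x$n_tests, x$hc_max, x$i_star))
  invisible(x)
}

#' Global rare/weak detection decision
#'
#' Rejects the global null (all p-values uniform) when the maximum of the
#' HC curve strictly exceeds the threshold. The default threshold 2 reads
#' each \eqn{HC_i} as an approximately standard normal z-score; because the
#' decision takes a maximum over many dependent ranks, this rule is
#' anticonservative for large `n` -- the package estimates (rather than
#' asserts) its null rejection rate, and the test suite reports it.
#'
#' @param curve An [hc_curve()] object, or a single numeric max-HC value.
#' @param threshold Decision threshold (default 2).
#' @return An object of class `hc_decision`: list with `hc_max`, `i_star`
#'   (NA when only a numeric maximum was supplied), `threshold`, `reject`,
#'   `n_tests`.
#' @export
hc_decide <- function(curve, threshold = 2) {
  if (inherits(curve, "hc_curve")) {
    hc_max <- curve$hc_max; i_star <- curve$i_star; n_tests <- curve$n_tests
  } else if (is.numeric(curve) && length(curve) == 1L) {
    hc_max <- curve; i_star <- NA_integer_; n_tests <- NA_integer_
  } else {
    stopf("`curve` must be an hc_curve or a single numeric value")
  }
  structure(list(hc_max = hc_max, i_star = i_star, threshold = threshold,
                 reject = hc_max > threshold, n_tests = n_tests),
            class = "hc_decision")
}

#' @export
print.hc_decision <- function(x, ...) {
  cat(sprintf("hc_decision: max HC = %.4f %s threshold %.2f -> %s\n",
              x$hc_max, if (x$reject) ">" else "<=", x$threshold,
              if (x$reject) "reject the global null" else "do not reject"))
  invisible(x)
}

#' Select the edges contributing to the maximum HC statistic
#'
#' The `i_star` smallest p-values -- the group of tests carrying the most
#' evidence against the global null -- mapped back to edge ids, each
#' annotated with the sign of its worry coefficient, its standardized
#' coefficient, and its p-value. Selection carries no per-edge type I
#' error control; it identifies likely contributors, not significant
#' edges.
#'
#' @param curve An [hc_curve()] built from `results$p`.
#' @param results The matching `edge_regression_results`.
#' @return A data frame of class `hc_selected` with columns
#'   `edge_id, p, beta, beta_std, sign`, ordered by ascending p, plus
#'   attributes `i_star` and `hc_max`.
#' @export
hc_select <- function(curve, results) {
  stopifnot(inherits(curve, "hc_curve"))
  if (curve$n_tests != nrow(results)) {
    stopf("curve was built from %d p-values but results has %d rows",
          curve$n_tests, nrow(results))
  }
  if (max(abs(results$p[curve$order] - curve$sorted_p)) > 1e-12) {
    stopf("`curve` does not match `results$p` (was it built from these results?)")
  }
  idx <- curve$order[seq_len(curve$i_star)]
  bstd <- standardized_beta(results)
  out <- data.frame(
    edge_id = results$edge_id[idx],
    p = results$p[idx],
    beta = results$beta[idx],
    beta_std = bstd[idx],
    sign = sign(results$beta[idx]),
    row.names = NULL
  )
  attr(out, "i_star") <- curve$i_star
  attr(out, "hc_max") <- curve$hc_max
  class(out) <- c("hc_selected", class(out))
  out
}
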