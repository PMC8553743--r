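#' Dichotomize a MADRS depression score
#'
#' The MADRS distribution in community late-life samples is highly skewed,
#' so it enters the design as a two-level factor rather than linearly.
#' The boundary value maps to `"high"` (`score >= threshold`).
#'
#' @param score Integer vector of MADRS scores (>= 0).
#' @param threshold Cut point; default 14.
#' @return Factor with levels `c("low", "high")`.
#' @examples
#' dichotomize_madrs(c(0, 7, 14, 30))
#' @export
dichotomize_madrs <- function(score, threshold = 14) {
  if (any(is.na(score)) || any(score < 0)) stopf("MADRS scores must be non-negative and non-missing")
  factor(ifelse(score >= threshold, "high", "low"), levels = c("low", "high"))
}

design_terms <- c("pswq", "age", "sex", "race", "education", "cirs_g",
                  "madrs_cat", "hars", "pss", "rsq", "neo_ffi")

#' Build the edge-wise regression design matrix
#'
#' Intercept, the worry score (PSWQ, predictor of interest), and the ten
#' adjustment covariates: age, sex, race, education, CIRS-G, dichotomized
#' MADRS, HARS, PSS, RSQ, NEO-FFI. Categoricals use treatment coding with
#' the most frequent observed level as reference, so with all three race
#' levels present `k = 13` columns (and `df = n - 13`).
#'
#' @param subjects A complete-case `subject_table`.
#' @param madrs_threshold Passed to [dichotomize_madrs()].
#' @param allow_degenerate If `TRUE`, a factor observed at a single level is
#'   dropped with a warning instead of raising an error.
#' @return An object of class `design_matrix`: list with `X` (n x k numeric
#'   matrix, first column the intercept), `worry_col` (column name of the
#'   PSWQ term), `references`, `n`, `k`, `df`, `sd_pswq`, `subject_id`.
#' @export
build_design_matrix <- function(subjects, madrs_threshold = 14,
                                allow_degenerate = FALSE) {
  req <- c("subject_id", "pswq", "age", "sex", "race", "education", "cirs_g",
           "madrs", "hars", "pss", "rsq", "neo_ffi")
  missing_cols <- setdiff(req, names(subjects))
  if (length(missing_cols)) stopf("subject table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (!all(stats::complete.cases(subjects[req]))) {
    stopf("subject table has missing values; the analysis set must be complete-case")
  }
  n <- nrow(subjects)
  if (n < 2L) stopf("at least 2 subjects are required")

  relevel_modal <- function(f) {
    f <- droplevels(factor(f))
    stats::relevel(f, ref = names(which.max(table(f))))
  }

  df <- data.frame(
    pswq = subjects$pswq, age = subjects$age,
    sex = relevel_modal(subjects$sex), race = relevel_modal(subjects$race),
    education = subjects$education, cirs_g = subjects$cirs_g,
    madrs_cat = dichotomize_madrs(subjects$madrs, madrs_threshold),
    hars = subjects$hars, pss = subjects$pss, rsq = subjects$rsq,
    neo_ffi = subjects$neo_ffi
  )
  df$madrs_cat <- droplevels(df$madrs_cat)

  terms_used <- design_terms
  for (fac in c("sex", "race", "madrs_cat")) {
    if (nlevels(df[[fac]]) < 2L) {
      if (allow_degenerate) {
        warnf("factor `%s` has a single observed level and was dropped from the design", fac)
        terms_used <- setdiff(terms_used, fac)
      } else {
        stopf("factor `%s` is constant; refit with allow_degenerate = TRUE to drop it", fac)
      }
    }
  }

  fml <- stats::as.formula(paste("~", paste(terms_used, collapse = " + ")))
  X <- stats::model.matrix(fml, data = df)
  colnames(X)[1] <- "(Intercept)"
  k <- ncol(X)
  if (n <= k) stopf("insufficient degrees of freedom: n = %d, k = %d", n, k)

  qx <- qr(X)
  if (qx$rank < k) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):k]]
    stopf("design matrix is rank deficient; aliased column(s): %s",
          paste(aliased, collapse = ", "))
  }

  refs <- list(madrs = "low")
  if ("sex" %in% terms_used) refs$sex <- levels(df$sex)[1]
  if ("race" %in% terms_used) refs$race <- levels(df$race)[1]
  structure(list(
    X = X, worry_col = "pswq", references = refs,
    n = n, k = k, df = n - k,
    sd_pswq = stats::sd(subjects$pswq),
    madrs_threshold = madrs_threshold,
    subject_id = as.character(subjects$subject_id)
  ), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: n = %d, k = %d, df = %d\n", x$n, x$k, x$df))
  cat("columns:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}

#' Fit the worry regression to every edge
#'
#' Ordinary least squares of each edge's Fisher-Z connectivity on the
#' design, vectorized across edges (all edges share one design, so the
#' normal equations are solved once). Reports, per edge, the worry
#' coefficient, its standard error, the t statistic, and the two-sided
#' p-value on `df = n - k` residual degrees of freedom.
#'
#' @param panel A [connectivity_panel()] (or bare numeric matrix, rows
#'   aligned with the design).
#' @param design A [build_design_matrix()] result.
#' @return A data frame of class `edge_regression_results` with columns
#'   `edge_id, beta, se, t, p`, ordered by edge id, and attributes `n`,
#'   `k`, `df`, `sd_pswq`.
#' @export
fit_edge_regressions <- function(panel, design) {
  stopifnot(inherits(design, "design_matrix"))
  Y <- if (inherits(panel, "connectivity_panel")) panel$z else as.matrix(panel)
  if (nrow(Y) != design$n) stopf("panel has %d rows but the design has %d", nrow(Y), design$n)
  if (inherits(panel, "connectivity_panel") &&
      !identical(panel$subject_id, design$subject_id)) {
    stopf("panel and design subject ids are misaligned")
  }
  if (any(!is.finite(Y))) stopf("panel entries must all be finite")

  X <- design$X
  w <- match(design$worry_col, colnames(X))
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, Y)           # k x E coefficients
  R <- Y - X %*% B
  sigma2 <- colSums(R^2) / design$df
  beta <- B[w, ]
  se <- sqrt(sigma2 * XtXi[w, w])
  t <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  p <- 2 * pt(abs(t), df = design$df, lower.tail = FALSE)

  out <- data.frame(edge_id = 0:(ncol(Y) - 1L), beta = beta, se = se,
                    t = t, p = p, row.names = NULL)
  attr(out, "n") <- design$n
  attr(out, "k") <- design$k
  attr(out, "df") <- design$df
  attr(out, "sd_pswq") <- design$sd_pswq
  class(out) <- c("edge_regression_results", class(out))
  out
}

#' Standardize worry coefficients
#'
#' `beta_std = beta * sd(PSWQ)`: the Fisher-Z change per 1 SD of worry.
#' This standardizes with respect to the predictor only, leaving the
#' outcome on the Fisher-Z scale. Supplying `sd_outcome` (e.g. per-edge
#' sample SDs) additionally divides by the outcome scale, giving a fully
#' standardized coefficient.
#'
#' @param results An `edge_regression_results` data frame.
#' @param sd_pswq SD of the worry score; defaults to the value recorded at
#'   fit time.
#' @param sd_outcome Optional per-edge outcome SDs; when supplied the
#'   coefficient is also divided by them (full standardization).
#' @return Numeric vector of standardized coefficients, one per edge.
#' @export
standardized_beta <- function(results, sd_pswq = attr(results, "sd_pswq"),
                              sd_outcome = NULL) {
  if (is.null(sd_pswq) || !is.finite(sd_pswq) || sd_pswq <= 0) {
    stopf("`sd_pswq` must be a positive number (zero worry variance?)")
  }
  out <- results$beta * sd_pswq
  if (!is.null(sd_outcome)) {
    if (any(sd_outcome <= 0)) stopf("`sd_outcome` must be positive")
    out <- out / sd_outcome
  }
  out
}
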