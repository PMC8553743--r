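#' Number of edges in an m-node connectome
#'
#' @param m Number of nodes (at least 1).
#' @return `m * (m - 1) / 2`, the number of unordered node pairs. A 212-node
#'   connectome has 22,366 edges.
#' @examples
#' edge_count(212)
#' @export
edge_count <- function(m) {
  m <- assert_count(m, "m", min = 1L)
  as.integer(m * (m - 1L) / 2L)
}

#' Canonical edge index for an m-node connectome
#'
#' Maps linear edge ids to node pairs. The canonical ordering is row-major
#' over the strict upper triangle of the correlation matrix:
#' (0,1), (0,2), ..., (0,m-1), (1,2), ..., (m-2,m-1). Every module in the
#' package shares this single ordering; node and edge ids are 0-based to
#' match the on-disk table conventions.
#'
#' @param m Number of nodes (at least 2).
#' @return A data frame of class `edge_index` with columns `edge_id`,
#'   `node_i`, `node_j` (`node_i < node_j`, all 0-based) and attribute `m`.
#' @examples
#' edge_index(4)
#' @export
edge_index <- function(m) {
  m <- assert_count(m, "m", min = 2L)
  node_i <- rep.int(0:(m - 2L), times = (m - 1L):1L)
  node_j <- sequence((m - 1L):1L, from = 1:(m - 1L))
  out <- data.frame(
    edge_id = 0:(edge_count(m) - 1L),
    node_i = as.integer(node_i),
    node_j = as.integer(node_j)
  )
  attr(out, "m") <- m
  class(out) <- c("edge_index", class(out))
  out
}

#' Fisher Z-transform of a correlation
#'
#' `atanh(r)`, the variance-stabilising transform that takes the sampling
#' distribution of a Pearson correlation to an approximately normal one.
#' Values with `|r| >= 1 - eps` are clamped to `1 - eps` (with a warning)
#' rather than mapped to infinity, so degenerate inputs degrade loudly but
#' gracefully.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @param eps Clamp tolerance; default `1e-7`.
#' @return `atanh` of the (possibly clamped) input. `tanh()` inverts it.
#' @examples
#' fisher_z(c(0, 0.5, 0.9))
#' @export
fisher_z <- function(r, eps = 1e-7) {
  if (any(is.na(r))) stopf("fisher_z: NaN/NA correlations are not allowed")
  if (any(abs(r) > 1)) stopf("fisher_z: correlations must lie in [-1, 1]")
  hi <- abs(r) >= 1 - eps
  if (any(hi)) {
    warnf("fisher_z: %d correlation(s) with |r| >= 1 - %g clamped", sum(hi), eps)
    r[hi] <- sign(r[hi]) * (1 - eps)
  }
  atanh(r)
}

#' Pearson correlation matrix of one subject's ROI time series
#'
#' @param series Numeric `T x m` matrix: `T` time points, `m` nodes
#'   (regions of interest). Requires `T >= 3` and no constant column.
#' @return `m x m` symmetric Pearson correlation matrix with unit diagonal.
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' roi_correlation_matrix(x)
#' @export
roi_correlation_matrix <- function(series) {
  series <- as.matrix(series)
  if (!is.numeric(series)) stopf("`series` must be a numeric matrix")
  if (nrow(series) < 3L) stopf("at least 3 time points are required (got %d)", nrow(series))
  sds <- apply(series, 2L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- which(sds == 0 | !is.finite(sds)) - 1L # 0-based node ids
    stopf("constant or non-finite time series at node id(s): %s",
          paste(bad, collapse = ", "))
  }
  cc <- stats::cor(series)
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  cc
}

#' Vectorize the strict upper triangle of a symmetric matrix
#'
#' Extracts the `m(m-1)/2` above-diagonal entries in the canonical row-major
#' order of [edge_index()].
#'
#' @param mat Square symmetric numeric matrix.
#' @return Numeric vector of length `m(m-1)/2` with attribute `m`.
#' @seealso [matrix_from_edges()] for the inverse.
#' @export
vectorize_upper <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stopf("`mat` must be square")
  if (max(abs(mat - t(mat))) > 1e-8) stopf("`mat` must be symmetric")
  # row-major upper triangle == column-major lower triangle of the transpose
  v <- t(mat)[lower.tri(mat)]
  attr(v, "m") <- nrow(mat)
  v
}

#' Rebuild a symmetric matrix from a canonical edge vector
#'
#' @param v Edge vector in canonical order (see [edge_index()]).
#' @param m Node count; defaults to the `m` attribute of `v`.
#' @param diag Value placed on the diagonal (default 1).
#' @return `m x m` symmetric matrix.
#' @export
matrix_from_edges <- function(v, m = attr(v, "m"), diag = 1) {
  if (is.null(m)) stopf("`m` is required when `v` carries no `m` attribute")
  m <- assert_count(m, "m", min = 2L)
  if (length(v) != edge_count(m)) stopf("length(v) != m(m-1)/2")
  out <- matrix(0, m, m)
  out[lower.tri(out)] <- v # fills column-major lower == canonical upper of t()
  out <- t(out)
  out <- out + t(out)
  diag(out) <- diag
  out
}

#' Construct a connectivity panel object
#'
#' A connectivity panel is the canonical subjects x edges matrix of Fisher
#' Z-transformed connectivities, the input to [fit_edge_regressions()].
#'
#' @param z Numeric `n_subjects x n_edges` matrix of Fisher-Z values.
#' @param m Node count consistent with `ncol(z) == m(m-1)/2`.
#' @param subject_id Character vector of subject ids (defaults to rownames).
#' @return An object of class `connectivity_panel`: list with elements `z`
#'   (the matrix, rows named by subject, columns `e0`, `e1`, ...), `m`, and
#'   `subject_id`.
#' @export
connectivity_panel <- function(z, m, subject_id = rownames(z)) {
  z <- as.matrix(z)
  m <- assert_count(m, "m", min = 2L)
  if (ncol(z) != edge_count(m)) {
    stopf("ncol(z) = %d but an %d-node connectome has %d edges",
          ncol(z), m, edge_count(m))
  }
  if (any(!is.finite(z))) stopf("connectivity panel entries must all be finite")
  if (is.null(subject_id)) subject_id <- paste0("S", seq_len(nrow(z)))
  if (length(subject_id) != nrow(z)) stopf("subject_id length != nrow(z)")
  rownames(z) <- subject_id
  colnames(z) <- paste0("e", 0:(ncol(z) - 1L))
  structure(list(z = z, m = m, subject_id = as.character(subject_id)),
            class = "connectivity_panel")
}

#' @export
print.connectivity_panel <- function(x, ...) {
  cat(sprintf("connectivity_panel: %d subjects x %d edges (%d nodes)\n",
              nrow(x$z), ncol(x$z), x$m))
  invisible(x)
}

#' Build a connectivity panel from a time-series panel
#'
#' For every subject: Pearson correlation matrix of the ROI series, strict
#' upper triangle in canonical order, Fisher Z-transform.
#'
#' @param ts_panel A `timeseries_panel` (see [simulate_timeseries()]) or a
#'   plain named list of `T x m` matrices.
#' @return A [connectivity_panel()].
#' @export
build_panel <- function(ts_panel) {
  series <- if (inherits(ts_panel, "timeseries_panel")) ts_panel$series else ts_panel
  if (!is.list(series) || length(series) == 0L) {
    stopf("`ts_panel` must contain at least one subject's series")
  }
  ms <- vapply(series, ncol, integer(1))
  if (length(unique(ms)) != 1L) stopf("all subjects must share the same node count")
  m <- ms[[1L]]
  ids <- names(series) %||% paste0("S", seq_along(series))
  z <- matrix(NA_real_, length(series), edge_count(m))
  for (s in seq_along(series)) {
    r <- tryCatch(
      vectorize_upper(roi_correlation_matrix(series[[s]])),
      error = function(e) stopf("subject %s: %s", ids[s], conditionMessage(e))
    )
    z[s, ] <- fisher_z(r)
  }
  connectivity_panel(z, m = m, subject_id = ids)
}
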