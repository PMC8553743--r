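#' Default cohort distribution configuration
#'
#' Marginal distributions emulating a late-life worry cohort (n = 77,
#' age > 50): continuous scores are normal with the published mean/SD,
#' clipped to instrument-valid ranges; non-negative, right-skewed clinical
#' scores (CIRS-G, MADRS, HARS) are moment-matched gammas rounded to
#' integers; sex and race are categorical. Any entry may be overridden.
#'
#' @param ... Named overrides, e.g. `pswq = list(mean = 50, sd = 10)`.
#' @return A list of per-covariate distribution specifications plus
#'   `p_female`, `race_probs`, and optional `psych_cor` (a named correlation
#'   matrix among continuous scores, applied through a Gaussian copula;
#'   `NULL` means independent margins).
#' @export
cohort_config <- function(...) {
  cfg <- list(
    age       = list(mean = 61.8, sd = 8.2,  lower = 40,  upper = 100, integer = FALSE),
    education = list(mean = 16.0, sd = 2.3,  lower = 6,   upper = 30,  integer = TRUE),
    pswq      = list(mean = 48.2, sd = 14.6, lower = 16,  upper = 80,  integer = TRUE),
    pss       = list(mean = 15.0, sd = 7.0,  lower = 0,   upper = 40,  integer = TRUE),
    rsq       = list(mean = 37.0, sd = 12.9, lower = 0,   upper = 88,  integer = TRUE),
    neo_ffi   = list(mean = 19.2, sd = 9.9,  lower = 0,   upper = 48,  integer = TRUE),
    cirs_g    = list(mean = 3.7,  sd = 3.5,  gamma = TRUE, integer = TRUE),
    madrs     = list(mean = 7.4,  sd = 7.9,  gamma = TRUE, integer = TRUE),
    hars      = list(mean = 7.4,  sd = 5.7,  gamma = TRUE, integer = TRUE),
    p_female  = 0.62,
    race_probs = c(W = 0.88, B = 0.10, MR = 0.01),
    psych_cor = NULL
  )
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg
}

continuous_fields <- c("age", "education", "pswq", "pss", "rsq", "neo_ffi",
                       "cirs_g", "madrs", "hars")

# Moments of X ~ N(mu, sd) clipped to [a, b].
clipped_normal_moments <- function(mu, sd, a, b) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  Fa <- pnorm(al); Fb <- pnorm(be)
  fa <- stats::dnorm(al); fb <- stats::dnorm(be)
  m1 <- a * Fa + b * (1 - Fb) + mu * (Fb - Fa) + sd * (fa - fb)
  mid2 <- mu^2 * (Fb - Fa) + 2 * mu * sd * (fa - fb) +
    sd^2 * ((Fb - Fa) - (be * fb - al * fa))
  m2 <- mid2 + a^2 * Fa + b^2 * (1 - Fb)
  c(mean = m1, sd = sqrt(pmax(m2 - m1^2, 0)))
}

# Pre-clip (mu, sd) such that the clipped variable hits the target moments.
clip_adjusted_params <- function(mean, sd, lower, upper) {
  mu <- mean; sg <- sd
  for (k in 1:30) {
    mm <- clipped_normal_moments(mu, sg, lower, upper)
    mu <- mu + (mean - mm[["mean"]])
    sg <- sg * sd / max(mm[["sd"]], 1e-12)
  }
  list(mean = mu, sd = sg)
}

# Quantile function for one configured margin, given uniforms.
margin_quantile <- function(u, spec) {
  if (isTRUE(spec$gamma)) {
    shape <- (spec$mean / spec$sd)^2
    scale <- spec$sd^2 / spec$mean
    x <- qgamma(u, shape = shape, scale = scale)
  } else {
    adj <- clip_adjusted_params(spec$mean, spec$sd, spec$lower, spec$upper)
    x <- qnorm(u, mean = adj$mean, sd = adj$sd)
    x <- pmin(pmax(x, spec$lower), spec$upper)
  }
  if (isTRUE(spec$integer)) x <- round(x)
  x
}

validate_cohort_config <- function(config) {
  for (f in continuous_fields) {
    spec <- config[[f]]
    if (is.null(spec$mean) || is.null(spec$sd)) stopf("config$%s needs mean and sd", f)
    if (spec$sd < 0) stopf("config$%s: sd must be non-negative", f)
    if (isTRUE(spec$gamma) && spec$mean <= 0) stopf("config$%s: gamma margin needs mean > 0", f)
  }
  if (config$p_female < 0 || config$p_female > 1) stopf("p_female must be in [0, 1]")
  rp <- config$race_probs
  if (any(rp < 0)) stopf("race probabilities must be non-negative")
  if (abs(sum(rp) - 1) > 0.05) stopf("race probabilities must sum to 1 (got %.3f)", sum(rp))
  if (!is.null(config$psych_cor)) {
    pc <- config$psych_cor
    if (is.null(dimnames(pc)) || !all(rownames(pc) %in% continuous_fields)) {
      stopf("psych_cor must be a correlation matrix with dimnames among the continuous scores")
    }
    ev <- eigen(pc, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stopf("psych_cor is not positive semi-definite")
  }
  invisible(config)
}

#' Simulate a subject covariate table
#'
#' Draws `n` subjects with worry score (PSWQ) and the ten adjustment
#' covariates used by the edge-wise regressions. Margins follow
#' [cohort_config()]; continuous scores are optionally correlated through a
#' Gaussian copula (`config$psych_cor`), and are otherwise independent.
#' The output is complete-case by construction.
#'
#' @param n Number of subjects (>= 0).
#' @param seed Integer seed; identical `(n, seed, config)` reproduce the
#'   identical table.
#' @param config Distribution configuration from [cohort_config()].
#' @return A data frame of class `subject_table` with columns
#'   `subject_id, age, sex, race, education, cirs_g, madrs, hars, pswq,
#'   pss, rsq, neo_ffi`.
#' @examples
#' simulate_subjects(5, seed = 1)
#' @export
simulate_subjects <- function(n, seed = 1L, config = cohort_config()) {
  n <- assert_count(n, "n")
  validate_cohort_config(config)
  empty <- data.frame(
    subject_id = character(0), age = numeric(0),
    sex = factor(character(0), levels = c("F", "M")),
    race = factor(character(0), levels = names(config$race_probs)),
    education = numeric(0), cirs_g = numeric(0), madrs = integer(0),
    hars = integer(0), pswq = numeric(0), pss = numeric(0),
    rsq = numeric(0), neo_ffi = numeric(0), stringsAsFactors = FALSE
  )
  if (n == 0L) {
    class(empty) <- c("subject_table", class(empty))
    return(empty)
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(assert_seed(seed))

  # uniforms for the continuous margins: independent, or copula-coupled
  u <- matrix(runif(n * length(continuous_fields)), n,
              dimnames = list(NULL, continuous_fields))
  if (!is.null(config$psych_cor)) {
    pc <- config$psych_cor
    vars <- rownames(pc)
    L <- chol(pc + diag(1e-10, nrow(pc)))
    zc <- matrix(rnorm(n * length(vars)), n) %*% L
    u[, vars] <- pnorm(zc)
  }

  vals <- lapply(continuous_fields, function(f) margin_quantile(u[, f], config[[f]]))
  names(vals) <- continuous_fields

  sex <- factor(ifelse(runif(n) < config$p_female, "F", "M"), levels = c("F", "M"))
  rp <- config$race_probs / sum(config$race_probs)
  race <- factor(sample(names(rp), n, replace = TRUE, prob = rp),
                 levels = names(rp))

  out <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = vals$age, sex = sex, race = race, education = vals$education,
    cirs_g = vals$cirs_g, madrs = as.integer(vals$madrs),
    hars = as.integer(vals$hars), pswq = vals$pswq, pss = vals$pss,
    rsq = vals$rsq, neo_ffi = vals$neo_ffi, stringsAsFactors = FALSE
  )
  class(out) <- c("subject_table", class(out))
  out
}

region_groups <- c("default mode", "limbic", "parietal", "prefrontal",
                   "sensorimotor", "subcortical", "temporal", "visual")

#' Build a node annotation table
#'
#' Assigns every node to one resting-state network and one anatomical
#' region group. The default configuration reproduces the 212-node
#' connectome: 79 default mode (DMN), 78 anterior salience (ASN), and 55
#' left executive control (LECN) nodes. Region groups are allocated within
#' each network by largest-remainder apportionment of the configured
#' proportions and assigned in a fixed cycle (optionally shuffled with
#' `seed`); the synthetic assignment carries no anatomical meaning, it only
#' exercises the region-level summaries.
#'
#' @param networks Named integer vector of node counts per network.
#' @param group_props Named proportions over the eight region groups.
#' @param seed Optional integer; if supplied, region-group assignment is
#'   shuffled reproducibly within each network.
#' @return A data frame of class `node_annotation` with columns
#'   `node_id` (0-based, contiguous), `label`, `network`, `region_group`,
#'   `hemisphere`.
#' @examples
#' table(make_node_annotation()$network)
#' @export
make_node_annotation <- function(networks = c(DMN = 79L, ASN = 78L, LECN = 55L),
                                 group_props = NULL, seed = NULL) {
  networks <- unlist(networks) # tolerate YAML-style named lists
  if (is.null(names(networks)) || any(!nzchar(names(networks)))) {
    stopf("`networks` must be a named vector of node counts")
  }
  if (any(networks < 1)) stopf("every network needs at least 1 node")
  if (is.null(group_props)) {
    group_props <- setNames(rep(1 / length(region_groups), length(region_groups)),
                            region_groups)
  }
  if (!all(names(group_props) %in% region_groups)) {
    stopf("unknown region group(s): %s",
          paste(setdiff(names(group_props), region_groups), collapse = ", "))
  }
  group_props <- group_props / sum(group_props)

  rows <- lapply(names(networks), function(nw) {
    k <- as.integer(networks[[nw]])
    # largest-remainder apportionment of region-group counts
    raw <- group_props * k
    cnt <- floor(raw)
    rem <- k - sum(cnt)
    if (rem > 0) {
      ord <- order(raw - cnt, decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
    }
    groups <- rep(names(group_props), times = cnt)
    if (!is.null(seed)) {
      old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
      set.seed(assert_seed(seed) + match(nw, names(networks)))
      groups <- sample(groups)
    }
    data.frame(
      label = sprintf("%s_%03d", nw, seq_len(k)),
      network = nw,
      region_group = groups,
      hemisphere = rep_len(c("L", "R"), k),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- data.frame(node_id = 0:(nrow(out) - 1L), out, stringsAsFactors = FALSE)
  out$network <- factor(out$network, levels = names(networks))
  out$region_group <- factor(out$region_group, levels = region_groups)
  out$hemisphere <- factor(out$hemisphere, levels = c("L", "R", "bilateral"))
  rownames(out) <- NULL
  class(out) <- c("node_annotation", class(out))
  out
}

#' Specify planted effects for the connectome generators
#'
#' Encodes the rare/weak regime: a sparse set of edges whose Fisher-Z
#' connectivity depends linearly on standardized worry, on top of a
#' baseline and Gaussian noise, with optional covariate confounding.
#'
#' @param planted_edges `NULL` or a data frame with columns `edge_id`
#'   (0-based, unique) and `beta` (Fisher-Z units per 1 SD of PSWQ).
#' @param baseline_z Fisher-Z intercept: scalar or one value per edge.
#' @param covariate_effects `NULL` or a data frame with columns `covariate`
#'   (a numeric subject-table column), `edge_id` (`NA` = all edges), and
#'   `slope` (Fisher-Z units per 1 SD of the covariate).
#' @param noise_sd Residual SD on the Fisher-Z scale (> 0 whenever any
#'   estimation is to be performed).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(planted_edges = NULL, baseline_z = 0,
                        covariate_effects = NULL, noise_sd = 0.3) {
  if (!is.null(planted_edges)) {
    if (!all(c("edge_id", "beta") %in% names(planted_edges))) {
      stopf("`planted_edges` needs columns edge_id and beta")
    }
    if (anyDuplicated(planted_edges$edge_id)) stopf("planted edge ids must be unique")
    if (any(planted_edges$edge_id < 0)) stopf("edge ids are 0-based and non-negative")
  }
  if (!is.null(covariate_effects) &&
      !all(c("covariate", "slope") %in% names(covariate_effects))) {
    stopf("`covariate_effects` needs columns covariate and slope")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stopf("`noise_sd` must be a single non-negative number")
  }
  structure(list(planted_edges = planted_edges, baseline_z = baseline_z,
                 covariate_effects = covariate_effects, noise_sd = noise_sd),
            class = "effect_spec")
}

# per-subject, per-edge mean Fisher-Z implied by an effect_spec
effect_mean_z <- function(subjects, effects, n_edges) {
  n <- nrow(subjects)
  base <- effects$baseline_z
  if (length(base) == 1L) base <- rep(base, n_edges)
  if (length(base) != n_edges) stopf("baseline_z must be scalar or one value per edge")
  mu <- matrix(rep(base, each = n), n, n_edges)

  pe <- effects$planted_edges
  if (!is.null(pe) && nrow(pe) > 0) {
    if (any(pe$edge_id >= n_edges)) stopf("planted edge id out of range (n_edges = %d)", n_edges)
    sdw <- stats::sd(subjects$pswq)
    if (!is.finite(sdw) || sdw == 0) stopf("PSWQ has zero variance; planted worry effects are undefined")
    w_std <- (subjects$pswq - mean(subjects$pswq)) / sdw
    mu[, pe$edge_id + 1L] <- mu[, pe$edge_id + 1L] + outer(w_std, pe$beta)
  }

  ce <- effects$covariate_effects
  if (!is.null(ce) && nrow(ce) > 0) {
    for (r in seq_len(nrow(ce))) {
      cv <- as.character(ce$covariate[r])
      if (!cv %in% names(subjects)) stopf("unknown covariate in effect spec: %s", cv)
      x <- subjects[[cv]]
      if (!is.numeric(x)) stopf("covariate effects require a numeric covariate (%s)", cv)
      xs <- (x - mean(x)) / max(stats::sd(x), 1e-12)
      eid <- ce$edge_id[r]
      cols <- if (is.null(eid) || is.na(eid)) seq_len(n_edges) else {
        if (eid >= n_edges) stopf("covariate effect edge id out of range")
        eid + 1L
      }
      mu[, cols] <- mu[, cols] + xs * ce$slope[r]
    }
  }
  mu
}

#' Simulate subject connectomes directly on the Fisher-Z scale
#'
#' For subject `s` and edge `e`,
#' `z[s, e] = baseline_z[e] + beta[e] * (pswq_s - mean) / sd + covariate
#' terms + Normal(0, noise_sd)`, with `beta[e] = 0` off the planted set.
#' Worry enters standardized, so planted betas are per-SD (standardized)
#' effects.
#'
#' @param subjects A `subject_table`.
#' @param annotation A `node_annotation` defining the node count.
#' @param effects An [effect_spec()].
#' @param seed Integer seed.
#' @return A [connectivity_panel()].
#' @export
simulate_connectomes <- function(subjects, annotation, effects = effect_spec(),
                                 seed = 1L) {
  stopifnot(inherits(effects, "effect_spec"))
  n <- nrow(subjects)
  if (n < 1L) stopf("at least 1 subject is required")
  m <- nrow(annotation)
  E <- edge_count(m)
  mu <- effect_mean_z(subjects, effects, E)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(assert_seed(seed))
  z <- mu + matrix(rnorm(n * E, sd = effects$noise_sd), n, E)
  connectivity_panel(z, m = m, subject_id = subjects$subject_id)
}

# eigenvalue-clipping nearest-positive-definite repair for a correlation matrix
nearest_pd_correlation <- function(C, eig_floor = 1e-8, repair_tol = 0.1) {
  ee <- eigen(C, symmetric = TRUE)
  if (min(ee$values) >= eig_floor) return(C)
  vals <- pmax(ee$values, eig_floor)
  R <- ee$vectors %*% (vals * t(ee$vectors))
  R <- stats::cov2cor(R)
  if (max(abs(R - C)) > repair_tol) {
    stopf("target correlation matrix is too far from positive definite (repair moved an entry by %.3f)",
          max(abs(R - C)))
  }
  R
}

#' Simulate band-limited ROI time series with target connectivity
#'
#' Per subject, the target node-node correlation matrix is obtained by
#' inverse Fisher-Z (`tanh`) of the subject's mean edge values under
#' `effects`, repaired to positive definite by eigenvalue clipping if
#' needed. White Gaussian series are band-limited by frequency-domain
#' masking, standardized, and then given the target spatial correlation by
#' a Cholesky factor, so sample correlations converge to the targets as `T`
#' grows. Defaults mirror a 6-minute resting-state scan: `T = 360` samples
#' at `tr = 1` s, pass-band 0.008-0.15 Hz.
#'
#' @param subjects A `subject_table`.
#' @param annotation A `node_annotation`.
#' @param effects An [effect_spec()] (Fisher-Z scale).
#' @param T_len Number of time points (>= 4).
#' @param tr Repetition time in seconds.
#' @param band Pass-band `(low, high)` in Hz with
#'   `0 < low < high < 1/(2 tr)`.
#' @param seed Integer seed.
#' @return An object of class `timeseries_panel`: list with `series` (one
#'   `T x m` matrix per subject, named by subject id), `tr`, `band`, `T`,
#'   `m`.
#' @export
simulate_timeseries <- function(subjects, annotation, effects = effect_spec(),
                                T_len = 360L, tr = 1.0,
                                band = c(0.008, 0.15), seed = 1L) {
  T_len <- assert_count(T_len, "T_len", min = 4L)
  n <- nrow(subjects)
  if (n < 1L) stopf("at least 1 subject is required")
  m <- nrow(annotation)
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] || band[2] >= 1 / (2 * tr)) {
    stopf("`band` must satisfy 0 < low < high < 1/(2*tr) = %.4f Hz", 1 / (2 * tr))
  }
  E <- edge_count(m)
  mu <- effect_mean_z(subjects, effects, E)

  freq <- (0:(T_len - 1L)) / (T_len * tr)
  freq <- pmin(freq, 1 / tr - freq) # two-sided spectrum folded to [0, Nyquist]
  keep <- freq >= band[1] & freq <= band[2]
  if (!any(keep)) stopf("pass-band retains no Fourier frequencies at T = %d, tr = %g", T_len, tr)

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(assert_seed(seed))
  series <- vector("list", n)
  for (s in seq_len(n)) {
    Ctar <- matrix_from_edges(tanh(mu[s, ]), m = m)
    Ctar <- nearest_pd_correlation(Ctar)
    wn <- matrix(rnorm(T_len * m), T_len, m)
    Fw <- stats::mvfft(wn)
    Fw[!keep, ] <- 0
    x <- Re(stats::mvfft(Fw, inverse = TRUE)) / T_len
    x <- scale(x, center = TRUE, scale = TRUE) # unit-variance band-limited noise
    series[[s]] <- x %*% chol(Ctar)
  }
  names(series) <- subjects$subject_id
  structure(list(series = series, tr = tr, band = band, T = T_len, m = m),
            class = "timeseries_panel")
}

#' @export
print.timeseries_panel <- function(x, ...) {
  cat(sprintf("timeseries_panel: %d subjects, T = %d, m = %d, tr = %gs, band = [%g, %g] Hz\n",
              length(x$series), x$T, x$m, x$tr, x$band[1], x$band[2]))
  invisible(x)
}
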