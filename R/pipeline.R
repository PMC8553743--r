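#' Default pipeline configuration
#'
#' The demonstration configuration mirrors the study conditions: 77
#' subjects, a 212-node connectome (79 DMN / 78 ASN / 55 LECN -> 22,366
#' edges), 100 planted edges carrying a standardized worry effect of 0.3
#' Fisher-Z units per SD of PSWQ amid noise of SD 0.3, and 100 bootstrap
#' iterations.
#'
#' @param out Output directory.
#' @param seed Master seed; every stage seed is derived from it.
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(out = "hcconnect-run", seed = 20210101L) {
  list(
    seed = seed,
    out = out,
    subjects = list(simulate = list(n = 77L)),
    annotation = list(simulate = list()),
    panel = list(simulate = list(n_planted = 100L, beta_per_sd = 0.3,
                                 baseline_z = 0, noise_sd = 0.3)),
    regression = list(madrs_threshold = 14),
    hc = list(threshold = 2, alpha0 = 1, plus = FALSE),
    bootstrap = list(B = 100L, threshold = 2),
    centrality_level = "region_group"
  )
}

validate_run_config <- function(config) {
  for (blk in c("subjects", "annotation", "panel")) {
    b <- config[[blk]]
    if (is.null(b) || (is.null(b$path) && is.null(b$simulate))) {
      stopf("config$%s must supply exactly one of `path` or `simulate`", blk)
    }
    if (!is.null(b$path) && !is.null(b$simulate)) {
      stopf("config$%s supplies both `path` and `simulate`; pick one", blk)
    }
  }
  if (is.null(config$seed)) stopf("config$seed is required")
  if (is.null(config$out)) stopf("config$out is required")
  invisible(config)
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline failed at stage `%s`: %s", stage, conditionMessage(e))
  })
}

#' Run the full connectome-wide higher-criticism pipeline
#'
#' Orchestrates simulate (or load) -> edge-wise regression -> HC curve,
#' decision, and selection -> bootstrap prevalence -> network summaries,
#' writing every intermediate artifact plus a reproducibility manifest to
#' the output directory. Re-running with an identical configuration
#' reproduces identical outputs (the manifest differs only in its
#' timestamp).
#'
#' @param config A configuration list (see [default_pipeline_config()]) or
#'   the path to a YAML file holding one.
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  validate_run_config(config)
  out <- config$out
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4L)
  names(seeds) <- c("subjects", "planted", "panel", "bootstrap")

  subjects <- run_stage("subjects", {
    if (!is.null(config$subjects$path)) {
      stage_msg("subjects", "reading %s", config$subjects$path)
      read_subjects_csv(config$subjects$path)
    } else {
      n <- config$subjects$simulate$n %||% 77L
      stage_msg("subjects", "simulating %d subjects (seed %d)", n, seeds[["subjects"]])
      simulate_subjects(n, seed = seeds[["subjects"]])
    }
  })
  write_subjects_csv(subjects, file.path(out, "subjects.csv"))

  annotation <- run_stage("annotation", {
    if (!is.null(config$annotation$path)) {
      stage_msg("annotation", "reading %s", config$annotation$path)
      read_annotation_csv(config$annotation$path)
    } else {
      stage_msg("annotation", "building default node annotation")
      do.call(make_node_annotation, config$annotation$simulate %||% list())
    }
  })
  write_annotation_csv(annotation, file.path(out, "nodes.csv"))
  m <- nrow(annotation)
  write_edge_index_csv(m, file.path(out, "edge_index.csv"))

  panel <- run_stage("panel", {
    if (!is.null(config$panel$path)) {
      stage_msg("panel", "reading %s", config$panel$path)
      read_panel_csv(config$panel$path, m = m)
    } else {
      ps <- config$panel$simulate
      E <- edge_count(m)
      n_planted <- ps$n_planted %||% 0L
      planted <- NULL
      if (n_planted > 0) {
        old <- get_rng_state()
        set.seed(seeds[["planted"]])
        planted <- data.frame(edge_id = sort(sample.int(E, n_planted) - 1L),
                              beta = ps$beta_per_sd %||% 0.3)
        restore_rng_state(old)
      }
      eff <- effect_spec(planted_edges = planted,
                         baseline_z = ps$baseline_z %||% 0,
                         noise_sd = ps$noise_sd %||% 0.3)
      stage_msg("panel", "simulating %d x %d Fisher-Z panel (%d planted edges, seed %d)",
                nrow(subjects), E, n_planted, seeds[["panel"]])
      simulate_connectomes(subjects, annotation, eff, seed = seeds[["panel"]])
    }
  })
  write_panel_csv(panel, file.path(out, "panel.csv"))

  design <- run_stage("regression", {
    build_design_matrix(subjects,
                        madrs_threshold = config$regression$madrs_threshold %||% 14)
  })
  results <- run_stage("regression", {
    stage_msg("regression", "fitting %d edge regressions (n = %d, k = %d, df = %d)",
              ncol(panel$z), design$n, design$k, design$df)
    fit_edge_regressions(panel, design)
  })
  res_out <- data.frame(results, beta_std = standardized_beta(results))
  utils::write.csv(res_out, file.path(out, "edge_results.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n = design$n, k = design$k, df = design$df,
         columns = colnames(design$X), references = design$references,
         sd_pswq = design$sd_pswq),
    file.path(out, "fit_manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  hc_cfg <- config$hc %||% list()
  curve <- run_stage("hc", {
    hc_curve(results$p, alpha0 = hc_cfg$alpha0 %||% 1,
             plus = isTRUE(hc_cfg$plus))
  })
  decision <- hc_decide(curve, threshold = hc_cfg$threshold %||% 2)
  selected <- hc_select(curve, results)
  stage_msg("hc", "max HC = %.3f at rank %d; reject = %s",
            curve$hc_max, curve$i_star, decision$reject)
  utils::write.csv(
    data.frame(rank = seq_len(curve$n_tests - 1L),
               p = curve$sorted_p[seq_len(curve$n_tests - 1L)],
               hc = curve$hc,
               edge_id = results$edge_id[curve$order[seq_len(curve$n_tests - 1L)]]),
    file.path(out, "hc_curve.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(hc_max = decision$hc_max, i_star = curve$i_star,
         threshold = decision$threshold, reject = decision$reject,
         n_tests = curve$n_tests),
    file.path(out, "decision.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(selected), file.path(out, "selected.csv"),
                   row.names = FALSE)

  bs_cfg <- config$bootstrap %||% list()
  B <- bs_cfg$B %||% 100L
  tally <- run_stage("bootstrap", {
    stage_msg("bootstrap", "B = %d subject resamples (seed %d)", B, seeds[["bootstrap"]])
    bootstrap_tally(subjects, panel, B = B,
                    threshold = bs_cfg$threshold %||% 2,
                    seed = seeds[["bootstrap"]],
                    madrs_threshold = config$regression$madrs_threshold %||% 14)
  })
  ranking <- rank_edges(tally, results)
  utils::write.csv(as.data.frame(tally), file.path(out, "tally.csv"), row.names = FALSE)
  utils::write.csv(ranking, file.path(out, "edge_ranking.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(B = attr(tally, "B"), B_informative = attr(tally, "B_informative"),
         threshold = attr(tally, "threshold"), seed = attr(tally, "seed"),
         redraws = attr(tally, "redraws"),
         is_significance_test = FALSE),
    file.path(out, "bootstrap_manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  counts <- run_stage("summaries", classify_edges(selected, annotation))
  centrality <- signed_degree_centrality(selected, annotation,
                                         level = config$centrality_level %||% "region_group")
  export_summary(selected, counts, centrality, annotation, out)
  stage_msg("summaries", "%d selected edges across %d signed network-pair cells",
            nrow(selected), 2L * nrow(counts))

  manifest <- list(
    package = "hcconnect",
    version = as.character(utils::packageVersion("hcconnect")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    seeds = as.list(seeds),
    n = design$n, k = design$k, df = design$df,
    n_nodes = m, n_edges = ncol(panel$z),
    hc_max = curve$hc_max, i_star = curve$i_star,
    threshold = decision$threshold, reject = decision$reject,
    n_selected = nrow(selected),
    B = attr(tally, "B"), B_informative = attr(tally, "B_informative"),
    stages = c("subjects", "annotation", "panel", "regression", "hc",
               "bootstrap", "summaries")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
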