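# Small fixtures shared across test files; everything is generated in code.

small_annotation <- function(dmn = 10L, asn = 8L, lecn = 7L) {
  make_node_annotation(c(DMN = dmn, ASN = asn, LECN = lecn))
}

# A cohort + null panel pair with aligned subject ids.
null_panel_fixture <- function(n = 60L, ann = small_annotation(),
                               noise_sd = 0.3, seed = 1L) {
  subj <- simulate_subjects(n, seed = seed)
  panel <- simulate_connectomes(subj, ann, effect_spec(noise_sd = noise_sd),
                                seed = seed + 1000L)
  list(subjects = subj, annotation = ann, panel = panel)
}

# A cohort + panel with k planted edges of standardized effect beta_sd.
planted_panel_fixture <- function(n = 150L, ann = small_annotation(),
                                  k = 20L, beta_sd = 0.3, noise_sd = 0.3,
                                  seed = 1L) {
  subj <- simulate_subjects(n, seed = seed)
  E <- edge_count(nrow(ann))
  planted <- data.frame(edge_id = 0:(k - 1L), beta = beta_sd)
  eff <- effect_spec(planted_edges = planted, noise_sd = noise_sd)
  panel <- simulate_connectomes(subj, ann, eff, seed = seed + 1000L)
  list(subjects = subj, annotation = ann, panel = panel,
       planted_ids = planted$edge_id)
}

# Hand-built selected-edge table (bypasses the regression) for summary tests.
manual_selected <- function(edge_id, beta_std, p = NULL, hc_max = 3, i_star = length(edge_id)) {
  out <- data.frame(
    edge_id = as.integer(edge_id),
    p = p %||% seq(1e-4, 1e-3, length.out = length(edge_id)),
    beta = beta_std / 14.6,
    beta_std = beta_std,
    sign = sign(beta_std)
  )
  attr(out, "i_star") <- i_star
  attr(out, "hc_max") <- hc_max
  class(out) <- c("hc_selected", class(out))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
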