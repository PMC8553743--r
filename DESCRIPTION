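Package: hcconnect
Title: Higher Criticism for Connectome-Wide Association Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Mass-univariate analysis of functional connectomes against a
    continuous phenotype, with higher criticism as the second-level test for
    rare and weak signal. Builds subjects-by-edges panels of Fisher
    Z-transformed Pearson connectivities from region-of-interest time series,
    fits covariate-adjusted linear models to every edge, computes the higher
    criticism curve over the ordered p-values, makes the global detection
    decision, selects the edges contributing to the maximum of the statistic,
    ranks edges by their prevalence across subject-resampling bootstrap
    iterations, and summarises selected edges at the network level (signed
    within/between-network counts and weighted degree centrality). Includes a
    synthetic cohort and connectome generator emulating a late-life worry
    study (212 nodes across the default mode, anterior salience, and left
    executive control networks) and a Monte Carlo power analysis for the
    max-HC detection rule in the rare/weak regime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
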