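---
title: "Higher criticism for connectome-wide association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Higher criticism for connectome-wide association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A functional connectome built over three canonical resting-state networks —
the default mode network (DMN, 79 nodes), the anterior salience network
(ASN, 78 nodes), and the left executive control network (LECN, 55 nodes) —
has 212 regions and therefore 22,366 pairwise connectivities. Asking how a
continuous phenotype such as worry severity (PSWQ, range 16–80) relates to
this connectome is a mass-univariate problem in the *rare/weak regime*: only
a small fraction of edges are expected to carry signal, and each individual
effect is expected to be too weak to survive family-wise or FDR correction
across 22,366 tests. `hcconnect` implements the full second-level analysis
for this setting:

1. **Edge panel.** Per subject, ROI time series → Pearson correlation
   matrix → canonical strict-upper-triangle vectorization → Fisher
   Z-transform (`atanh`), giving a subjects × edges panel.
2. **Edge-wise regression.** Each edge's Fisher-Z value is regressed on
   PSWQ plus ten confounds (age, sex, race, education, CIRS-G, dichotomized
   MADRS, HARS, PSS, RSQ, NEO-FFI); the worry coefficient, its *t*
   statistic, and a two-sided p-value are retained per edge.
3. **Higher criticism.** The ordered p-values are compared against the
   uniform null at every rank,
   $$\mathrm{HC}_i = \sqrt{n}\,\frac{i/n - p_{(i)}}{\sqrt{(i/n)(1-i/n)}},
   \qquad i = 1,\dots,n-1,$$
   the maximum over ranks is the global detection statistic (reject when it
   strictly exceeds a threshold, default 2), and the argmax rank defines the
   selected edge set — the group of tests contributing the most evidence
   against the global null. Selection carries no per-edge type I error
   control.
4. **Bootstrap prevalence.** Subjects are resampled with replacement; per
   iteration the design is rebuilt, all edges refit, and HC recomputed.
   When the maximum HC statistic reaches the threshold, each selected edge's
   tally is incremented. Prevalence ranks edge importance; it is explicitly
   not a significance test.
5. **Network summaries.** Selected edges are classified into the six signed
   within/between-network categories, and signed weighted degree centrality
   (the per-region sum of worry-standardized coefficients, positive and
   negative strata kept separate to avoid cancellation) is exported as
   plotting-ready tables.

A Monte-Carlo power module (`simulate_power`, `minimal_n_for_power`)
evaluates the max-HC rule at design stage, and a synthetic cohort module
makes the whole pipeline testable end to end without any data download.

## The synthetic cohort and what it does (not) emulate

`simulate_subjects()` draws the twelve covariates from marginal
distributions matching the emulated cohort's published summary statistics
(age 61.8 ± 8.2, education 16.0 ± 2.3, PSWQ 48.2 ± 14.6, RSQ 37.0 ± 12.9,
NEO-FFI 19.2 ± 9.9, CIRS-G 3.7 ± 3.5, MADRS 7.4 ± 7.9, HARS 7.4 ± 5.7,
62% female, race split 88/10/1 normalised to probabilities). Choices worth
knowing about:

* **Skewed clinical scores.** MADRS, HARS, and CIRS-G are non-negative and
  right-skewed in community late-life samples (the skew is exactly why
  MADRS is dichotomized at 14 in the regression), so they are drawn from
  gamma distributions moment-matched to the published mean/SD and rounded
  to integers.
* **Clipping without moment distortion.** Normal scores are clipped to
  instrument ranges (PSWQ to [16, 80], NEO-FFI to [0, 48], ...). Naïve
  clipping shrinks the delivered SD by a few percent, which is enough to
  fail a 3-standard-error fidelity check at n = 20,000; the generator
  therefore pre-adjusts the parent mean/SD by fixed-point iteration on the
  analytic clipped-normal moments so the *delivered* scores match the
  configured moments.
* **PSS default.** The perceived-stress scale has no published summary in
  the emulated cohort; the default (15 ± 7 on the 0–40 PSS-10 scale) is a
  realistic profile for community-dwelling older adults and is a one-time
  choice, configurable like every other margin.
* **Age guard range.** Ages are drawn at the published 61.8 ± 8.2 with a
  wide guard range [40, 100] rather than a hard eligibility truncation at
  50; truncating at 50 would bias the delivered mean/SD away from the
  published values, and the eligibility boundary is irrelevant to the
  statistics being exercised.
* **Independence by default.** Only marginals are published, so covariates
  are independent by default. Because the real constructs (worry,
  rumination, neuroticism, anxiety) are strongly correlated, a Gaussian
  copula over any subset of the continuous scores can be supplied via
  `cohort_config(psych_cor = ...)`; tests exercise it at r = 0.6.

`simulate_connectomes()` generates edges directly on the Fisher-Z scale:
`z[s, e] = baseline_z[e] + beta[e] · (pswq_s − mean)/sd + covariate terms +
N(0, noise_sd)`. Planted betas are therefore *standardized* effects
(Fisher-Z units per SD of worry) — the same scale on which the power module
interprets "effect size". The default `noise_sd = 0.3` is a realistic
between-subject SD for a single edge's Fisher-Z value in resting-state
panels. `simulate_timeseries()` instead generates band-limited Gaussian ROI
series (default T = 360 samples at tr = 1 s, pass-band 0.008–0.15 Hz,
mirroring a 6-minute scan) whose population correlation matrix equals the
subject's target (inverse Fisher-Z of the mean edge values, repaired to
positive definite by eigenvalue clipping at 1e−8 when planted structure
makes it slightly indefinite; a repair that moves any entry by more than
0.1 is an error rather than a silent rewrite).

What passing tests on these generators do **not** show about real fMRI:
there is no hemodynamic response, no motion or scanner artifact, no
spatial autocorrelation between edges sharing a node beyond what the
planted structure induces, and the synthetic region-group assignment is
proportional bookkeeping, not anatomy. The suite demonstrates statistical
correctness of the pipeline, not robustness to preprocessing failures.

## Numerical and design choices

* **Canonical edge order.** Row-major strict upper triangle, 0-based ids,
  shared by every module and written to an `edge_index.csv` sidecar. A
  single convention prevents silent edge misalignment between panel,
  results, selection, and summaries.
* **Edge-wise OLS.** All 22,366 regressions share one design matrix, so the
  normal equations are solved once (`chol2inv(chol(X'X))`) and applied to
  all edges; the suite verifies equality with independent single-edge
  `lm()` fits to 1e−10. p-values use the exact *t* distribution on
  `n − k` degrees of freedom (df = 64 at n = 77, k = 13, where *t* and *z*
  are practically indistinguishable); finite-sample calibration is what the
  null-uniformity tests check.
* **Reference levels.** Treatment coding with the modal category as
  reference (sex → F, race → W under the default mix); the MADRS factor
  references "low", and the boundary score 14 maps to "high". None of this
  affects the worry coefficient; it is fixed for reproducibility.
* **HC index range.** The statistic is evaluated at ranks 1..n−1 — the
  rank-n term has zero binomial variance and is undefined. The default is
  the plain statistic over the full range; `alpha0` (restrict to
  `i/n ≤ α₀`) and `plus` (ignore `p_(i) < 1/n`) stabilizations are
  available but off by default, favouring fidelity to the plain formula.
* **Ties and zeros.** p-value sorting is stable (ties keep input order), a
  tied maximum resolves to the smallest rank, and p-values of exactly 0
  (underflow upstream) are floored at 1e−300 with a warning.
* **Threshold 2 is anticonservative.** Reading each HC rank as a standard
  normal z-score motivates the threshold of 2, but the decision takes a
  maximum over thousands of dependent ranks, which grows like
  $\sqrt{2\log\log n}$ under the null. At n = 22,366 the measured null
  rejection rate of the threshold-2 full-range rule is roughly 0.7, and the
  test suite reports (rather than asserts) this rate. The global decision
  uses strict `>`; the bootstrap tally rule uses `≥`, the complement of
  "below threshold tallies nothing". Both thresholds are configurable.
* **Bootstrap reproducibility.** One child seed per iteration is pre-drawn
  from the master seed, making the tally independent of iteration order.
  Resamples that collapse a factor level (breaking the design rank) are
  redrawn and counted; more than 50% redraws aborts as a degenerate design.
* **Bootstrap prevalence is not inference.** Within one dataset, resamples
  share the observed data: an edge with a small full-sample p-value is
  re-selected in nearly every iteration, so prevalences are strongly
  dependent and far from Binomial(B, p̄). The tally output carries
  `is_significance_test = FALSE`, and the null-behaviour test checks the
  meaningful property — that no edge is a stable top selection *across*
  independent null datasets.

## The power module and its honest result

`simulate_power()` implements the design-stage calculation: a standardized
worry vector, `n_features` unit-variance Gaussian outcomes of which
`k_nonnull` have population correlation `effect` with worry, two-sided
p-values from the simple-regression *t*, and the max-HC threshold-2
decision. "Effect size 0.1" is interpreted as that population correlation
(equivalently the standardized simple-regression slope) — the only
dimensionless reading of 0.1 — and covariates are treated as orthogonal
noise at design stage. `minimal_n_for_power()` evaluates a grid of sample
sizes with common random numbers (each simulation draws its cohort once at
the largest n; smaller n use the leading rows), and can extend the grid
upward so the returned minimal n is always a measured quantity.

Two facts shape the results. First, at 22,366 features, 100 non-null
features with correlation 0.1 at n ≈ 81 sit essentially on the
detection-boundary of the rare/weak phase diagram (per-feature
noncentrality ≈ 0.1·√81 = 0.9 against a sparsity exponent of ≈ 0.54) — a
regime where higher criticism succeeds asymptotically but finite-sample
power is moderate. Second, because the threshold-2 rule already rejects
~70% of nulls, its empirical "power" at small effects is dominated by the
null rate and climbs very slowly with n: in this package's measurements it
does not reach 80% until n is in the low hundreds. The acceptance script
therefore reports the measured minimal n over an extended grid rather than
a value tuned to any expectation. Users who want a calibrated detection
rule should simulate their own null critical value at their feature count
(the reported null rejection rate makes this straightforward) instead of
relying on the asymptotic threshold.

## Problem sizes used by the test suite

Module tests run on reduced connectomes (21–102 nodes, 210–5,151 edges)
with cohorts of 30–200 subjects and 4–100 bootstrap iterations; the
end-to-end demonstration and the recovery properties run at the full
212-node, 22,366-edge scale with 77–200 subjects and B = 100. Power
simulations use 200 replicates per grid point (Monte-Carlo SE ≈ 0.03 at
power 0.8). Distributional-fidelity checks use n = 10,000–20,000 subjects.
These sizes were chosen so the whole suite exercises every full-scale code
path while remaining desk-scale.

## Known limitations

* The pipeline assumes clean ROI series: despiking, nuisance regression,
  and motion handling are upstream concerns.
* No partial correlations, regularized covariance, or windowed (dynamic)
  connectivity.
* No robust or heteroskedasticity-consistent standard errors; no mixed
  models or site harmonization.
* No analytic max-HC critical values (detection-boundary asymptotics); the
  null rejection rate is estimated empirically.
* The HC selection step deliberately offers no per-edge error control —
  downstream interpretation should treat selected edges as ranked
  candidates, exactly as the bootstrap-prevalence output labels them.
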