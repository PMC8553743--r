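test_that("simulate_subjects returns a complete, instrument-valid table", {
  s <- simulate_subjects(200, seed = 4)
  expect_s3_class(s, "subject_table")
  expect_equal(nrow(s), 200)
  expect_false(anyNA(s))
  expect_true(all(s$pswq >= 16 & s$pswq <= 80))
  expect_true(all(s$madrs >= 0 & s$madrs == round(s$madrs)))
  expect_true(all(s$hars >= 0))
  expect_true(all(s$cirs_g >= 0))
  expect_setequal(levels(s$sex), c("F", "M"))
})

test_that("n = 0 yields an empty table with the full header", {
  s <- simulate_subjects(0, seed = 1)
  expect_equal(nrow(s), 0)
  expect_identical(names(s), c("subject_id", "age", "sex", "race", "education",
                               "cirs_g", "madrs", "hars", "pswq", "pss",
                               "rsq", "neo_ffi"))
})

test_that("the generator is a pure function of (n, seed, config)", {
  a <- simulate_subjects(50, seed = 7)
  b <- simulate_subjects(50, seed = 7)
  expect_identical(a, b)
  c <- simulate_subjects(50, seed = 8)
  expect_false(identical(a, c))
})

test_that("large-sample PSWQ moments match the configured cohort profile", {
  s <- simulate_subjects(10000, seed = 21)
  expect_lt(abs(mean(s$pswq) - 48.2), 0.5)
  expect_lt(abs(sd(s$pswq) - 14.6), 0.5)
})

test_that("every continuous covariate hits its configured mean/SD within 3 SE", {
  n <- 20000
  s <- simulate_subjects(n, seed = 31)
  cfg <- cohort_config()
  for (f in c("age", "education", "pswq", "pss", "rsq", "neo_ffi",
              "cirs_g", "madrs", "hars")) {
    mu <- cfg[[f]]$mean; sg <- cfg[[f]]$sd
    expect_lt(abs(mean(s[[f]]) - mu), 3 * sg / sqrt(n), label = paste(f, "mean"))
    # SE of a sample SD under approximate normality is sg / sqrt(2n)
    expect_lt(abs(sd(s[[f]]) - sg), 3 * sg / sqrt(2 * n) + 0.05, label = paste(f, "sd"))
  }
  expect_lt(abs(mean(s$sex == "F") - 0.62), 3 * sqrt(0.62 * 0.38 / n))
})

test_that("a psychometric copula induces the requested correlation", {
  pc <- matrix(c(1, 0.6, 0.6, 1), 2, 2,
               dimnames = list(c("pswq", "rsq"), c("pswq", "rsq")))
  s <- simulate_subjects(5000, seed = 41, config = cohort_config(psych_cor = pc))
  expect_lt(abs(cor(s$pswq, s$rsq) - 0.6), 0.05)
  # independent by default
  s0 <- simulate_subjects(5000, seed = 41)
  expect_lt(abs(cor(s0$pswq, s0$rsq)), 0.05)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(simulate_subjects(-1, seed = 1), "integer")
  expect_error(simulate_subjects(10, seed = 1,
                                 config = cohort_config(race_probs = c(W = 0.5, B = 0.1, MR = 0.1))),
               "sum to 1")
  expect_error(simulate_subjects(10, seed = 1,
                                 config = cohort_config(pswq = list(mean = 48, sd = -1, lower = 16, upper = 80))),
               "sd")
})

test_that("the default annotation is the 212-node three-network connectome", {
  ann <- make_node_annotation()
  expect_equal(nrow(ann), 212)
  expect_equal(as.vector(table(ann$network)[c("DMN", "ASN", "LECN")]),
               c(79, 78, 55))
  expect_identical(ann$node_id, 0:211)
  groups <- c("default mode", "limbic", "parietal", "prefrontal",
              "sensorimotor", "subcortical", "temporal", "visual")
  expect_true(all(as.character(ann$region_group) %in% groups))
  expect_false(anyNA(ann))
  # deterministic
  expect_identical(ann, make_node_annotation())
})

test_that("minimal and invalid annotation configurations behave", {
  ann3 <- make_node_annotation(c(DMN = 1, ASN = 1, LECN = 1))
  expect_equal(nrow(ann3), 3)
  expect_equal(length(unique(ann3$network)), 3)
  expect_error(make_node_annotation(c(DMN = 0, ASN = 1, LECN = 1)), "at least 1")
  expect_error(make_node_annotation(c(5, 5)), "named")
})

test_that("simulate_connectomes plants the configured linear structure", {
  ann <- small_annotation()
  subj <- simulate_subjects(2000, seed = 51)
  eff <- effect_spec(planted_edges = data.frame(edge_id = 3L, beta = 0.3),
                     baseline_z = 0.1, noise_sd = 0.3)
  panel <- simulate_connectomes(subj, ann, eff, seed = 52)
  # closed-form OLS of the planted edge on standardized worry recovers 0.3
  w <- (subj$pswq - mean(subj$pswq)) / sd(subj$pswq)
  z <- panel$z[, 4]
  bhat <- sum((w - mean(w)) * z) / sum((w - mean(w))^2)
  se <- sqrt(sum((z - mean(z) - bhat * (w - mean(w)))^2) / (2000 - 2) / sum((w - mean(w))^2))
  # 3-SE band: a fixed-seed draw misses a 1.96-SE band 5% of the time by
  # construction; unbiasedness at the 2-SE level is checked over 200
  # replicates below
  expect_lt(abs(bhat - 0.3), 3 * se)
  # unplanted edges sit at the baseline
  expect_lt(abs(mean(panel$z[, 10]) - 0.1), 0.05)
})

test_that("a noise-free panel is constant at the baseline", {
  ann <- small_annotation()
  subj <- simulate_subjects(20, seed = 61)
  panel <- simulate_connectomes(subj, ann, effect_spec(baseline_z = 0.25, noise_sd = 0),
                                seed = 62)
  expect_true(all(abs(panel$z - 0.25) < 1e-12))
})

test_that("connectome simulation is deterministic and validates edge ids", {
  ann <- small_annotation()
  subj <- simulate_subjects(10, seed = 71)
  eff <- effect_spec(planted_edges = data.frame(edge_id = 0L, beta = 0.2))
  p1 <- simulate_connectomes(subj, ann, eff, seed = 72)
  p2 <- simulate_connectomes(subj, ann, eff, seed = 72)
  expect_identical(p1$z, p2$z)
  bad <- effect_spec(planted_edges = data.frame(edge_id = edge_count(nrow(ann)), beta = 0.2))
  expect_error(simulate_connectomes(subj, ann, bad, seed = 72), "out of range")
  expect_error(effect_spec(planted_edges = data.frame(edge_id = c(1, 1), beta = 0.2)),
               "unique")
})

test_that("planted betas are recovered without bias across replicates", {
  ann <- make_node_annotation(c(DMN = 2, ASN = 2, LECN = 2))
  est <- vapply(1:200, function(r) {
    subj <- simulate_subjects(40, seed = 5000 + r)
    eff <- effect_spec(planted_edges = data.frame(edge_id = 0L, beta = 0.25),
                       noise_sd = 0.3)
    panel <- simulate_connectomes(subj, ann, eff, seed = 6000 + r)
    w <- (subj$pswq - mean(subj$pswq)) / sd(subj$pswq)
    sum((w - mean(w)) * panel$z[, 1]) / sum((w - mean(w))^2)
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.25), 2 * mc_se)
})
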