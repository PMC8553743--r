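test_that("an empty selection yields all-zero counts and centrality", {
  ann <- small_annotation()
  sel <- manual_selected(integer(0), numeric(0))
  counts <- classify_edges(sel, ann)
  expect_equal(nrow(counts), 6)
  expect_true(all(counts$positive == 0) && all(counts$negative == 0))
  cent <- signed_degree_centrality(sel, ann, level = "region_group")
  expect_true(all(cent$positive_sum == 0) && all(cent$negative_sum == 0))
})

test_that("a single within-DMN negative edge lands in exactly one cell", {
  ann <- small_annotation(10, 8, 7)
  # edge 0 joins nodes 0 and 1, both DMN
  sel <- manual_selected(0L, -0.2)
  counts <- classify_edges(sel, ann)
  expect_equal(counts$negative[counts$category == "DMN"], 1)
  expect_equal(sum(counts$positive) + sum(counts$negative), 1)
})

test_that("a ten-edge selection matches hand enumeration", {
  # m = 6: nodes 0,1 DMN; 2,3 ASN; 4,5 LECN; edges in canonical order:
  # (0,1)(0,2)(0,3)(0,4)(0,5)(1,2)(1,3)(1,4)(1,5)(2,3)(2,4)(2,5)(3,4)(3,5)(4,5)
  ann <- make_node_annotation(c(DMN = 2, ASN = 2, LECN = 2))
  ids <- c(0, 1, 3, 5, 9, 10, 12, 14, 4, 13)
  w <- c(0.1, -0.2, 0.3, -0.1, 0.2, 0.15, -0.25, 0.05, 0.3, 0.1)
  sel <- manual_selected(ids, w)
  counts <- classify_edges(sel, ann)
  # hand-placed: 0:(0,1) DMN +, 1:(0,2) DMN-ASN -, 3:(0,4) LECN-DMN +,
  # 5:(1,2) DMN-ASN -, 9:(2,3) ASN +, 10:(2,4) ASN-LECN +,
  # 12:(3,4) ASN-LECN -, 14:(4,5) LECN +, 4:(0,5) LECN-DMN +, 13:(3,5) ASN-LECN +
  get <- function(cat, col) counts[[col]][counts$category == cat]
  expect_equal(get("DMN", "positive"), 1)
  expect_equal(get("DMN", "negative"), 0)
  expect_equal(get("ASN", "positive"), 1)
  expect_equal(get("LECN", "positive"), 1)
  expect_equal(get("DMN-ASN", "negative"), 2)
  expect_equal(get("ASN-LECN", "positive"), 2)
  expect_equal(get("ASN-LECN", "negative"), 1)
  expect_equal(get("LECN-DMN", "positive"), 2)
  expect_equal(sum(counts$positive) + sum(counts$negative), 10)
})

test_that("classification is symmetric in the edge's endpoints", {
  # interleaved networks produce both endpoint orders for the same pair
  ann <- make_node_annotation(c(DMN = 2, LECN = 2))
  ann$network <- factor(c("DMN", "LECN", "LECN", "DMN"),
                        levels = c("DMN", "LECN"))
  # edge (0,1): DMN then LECN; edge (2,3): LECN then DMN
  sel <- manual_selected(c(0L, 5L), c(0.1, 0.1))
  counts <- classify_edges(sel, ann)
  expect_equal(counts$positive[counts$category == "LECN-DMN"], 2)
})

test_that("zero-coefficient edges count as positive with a warning", {
  ann <- small_annotation(4, 3, 3)
  sel <- manual_selected(0L, 0)
  expect_warning(counts <- classify_edges(sel, ann), "beta = 0")
  expect_equal(sum(counts$positive), 1)
})

test_that("the twelve cells always sum to the selection size", {
  ann <- small_annotation()
  set.seed(30)
  for (rep in 1:5) {
    k <- sample(50, 1)
    sel <- manual_selected(sample(edge_count(25), k) - 1L, rnorm(k))
    counts <- classify_edges(sel, ann)
    expect_equal(sum(counts$positive) + sum(counts$negative), k)
  }
})

test_that("single-edge centrality credits both endpoints", {
  ann <- small_annotation(10, 8, 7)
  sel <- manual_selected(0L, 0.3) # nodes 0 and 1
  cent <- signed_degree_centrality(sel, ann, level = "node")
  lab <- ann$label[ann$node_id %in% c(0, 1)]
  expect_equal(cent$positive_sum[cent$region %in% lab], c(0.3, 0.3))
  expect_equal(sum(cent$positive_sum), 0.6)
  expect_true(all(cent$negative_sum == 0))
})

test_that("the centrality handshake identity holds on random selections", {
  ann <- small_annotation()
  set.seed(31)
  for (level in c("node", "region_group")) {
    k <- 40
    sel <- manual_selected(sample(edge_count(25), k) - 1L, rnorm(k))
    cent <- signed_degree_centrality(sel, ann, level = level)
    expect_true(all(cent$positive_sum >= 0))
    expect_true(all(cent$negative_sum <= 0))
    expect_equal(sum(cent$positive_sum) - sum(cent$negative_sum),
                 2 * sum(abs(sel$beta_std)), tolerance = 1e-12)
  }
})

test_that("region-group centrality aggregates the node-level map", {
  ann <- small_annotation()
  set.seed(32)
  sel <- manual_selected(sample(edge_count(25), 20) - 1L, rnorm(20))
  node_map <- signed_degree_centrality(sel, ann, level = "node")
  group_map <- signed_degree_centrality(sel, ann, level = "region_group")
  agg <- tapply(node_map$positive_sum, ann$region_group[match(node_map$region, ann$label)], sum)
  for (g in group_map$region) {
    expected <- unname(agg[g])
    if (is.na(expected)) expected <- 0
    expect_equal(group_map$positive_sum[group_map$region == g],
                 expected, tolerance = 1e-12)
  }
})

test_that("export_summary writes consistent, byte-stable artifacts", {
  ann <- small_annotation(4, 3, 3)
  set.seed(33)
  sel <- manual_selected(sample(edge_count(10), 10) - 1L, rnorm(10),
                         hc_max = 3.21, i_star = 10)
  counts <- classify_edges(sel, ann)
  cent <- signed_degree_centrality(sel, ann, level = "region_group")
  dir1 <- withr::local_tempdir()
  paths <- export_summary(sel, counts, cent, ann, dir1)
  expect_true(all(file.exists(paths)))
  tab <- read.csv(paths[["counts"]])
  expect_equal(nrow(tab), 6)
  expect_equal(sum(tab$positive) + sum(tab$negative), 10)
  smry <- jsonlite::read_json(paths[["summary"]])
  expect_equal(smry$n_selected, nrow(read.csv(paths[["edges"]])))
  expect_equal(smry$hc_max, 3.21)
  # identical inputs re-export byte-identically
  dir2 <- withr::local_tempdir()
  paths2 <- export_summary(sel, counts, cent, ann, dir2)
  for (nm in names(paths)) {
    expect_identical(readLines(paths[[nm]]), readLines(paths2[[nm]]),
                     label = nm)
  }
})
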