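small_params <- function(seed, ...) {
  synthetic_params(seed = seed, n_modules = 3L, genes_per_module = 12L,
                   n_bridge_genes = 3L, n_peripheral_genes = 6L,
                   n_background_genes = 10L, ...)
}

test_that("generation is bit-reproducible from the seed", {
  d1 <- generate_dataset(small_params(31))
  d2 <- generate_dataset(small_params(31))
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(small_params(32))
  expect_false(identical(d1$expression, d3$expression))
})

test_that("dimensions follow the design arithmetic", {
  p <- small_params(7, duplicate_probe_fraction = 0.2)
  d <- generate_dataset(p)
  n_genes <- 3 * 12 + 3 + 6 + 10
  n_dup <- round(0.2 * n_genes)
  expect_equal(nrow(d$expression), n_genes + n_dup)
  expect_identical(ncol(d$expression),
                   length(p$conditions) * length(p$timepoints) * p$replicates +
                     p$n_baseline_controls)
  expect_identical(ncol(d$expression), nrow(d$design))
  expect_identical(sum(d$design$is_baseline_control), 6L)
  # duplicate probes re-measure existing genes
  expect_identical(sort(unique(unname(d$truth$probe_gene))),
                   sort(names(d$truth$gene_module)))
  validate_design(d$expression, d$design)
})

test_that("same-module genes approach perfect correlation as noise vanishes", {
  d <- generate_dataset(small_params(3, noise_sd = 1e-6))
  m1 <- names(d$truth$gene_module)[d$truth$gene_module == "M1"][1:2]
  probes <- names(d$truth$probe_gene)[match(m1, d$truth$probe_gene)]
  expect_gt(cor(d$expression[probes[1], ], d$expression[probes[2], ]), 0.9999)
})

test_that("module gene sets are disjoint and decoys are size-matched", {
  d <- generate_dataset(small_params(11))
  sets <- generate_gene_sets(d$truth, n_decoys = 10)
  expect_identical(length(sets), 13L)
  mods <- sets[grepl("^MOD_", names(sets))]
  expect_identical(length(unique(unlist(mods))), 3L * 12L)  # no overlap
  expect_false(any(grepl("^BRDG", unlist(mods))))
  expect_setequal(unique(lengths(sets[grepl("^DECOY_", names(sets))])), 12L)
})

test_that("knockdown matrices reflect shared regulators and are reproducible", {
  d <- generate_dataset(small_params(13))
  k1 <- generate_knockdown_matrix(d$truth, n_regulators = 40, seed = 5)
  k2 <- generate_knockdown_matrix(d$truth, n_regulators = 40, seed = 5)
  expect_identical(k1, k2)
  expect_identical(dim(k1), c(length(d$truth$gene_module), 40L))

  m1 <- names(d$truth$gene_module)[d$truth$gene_module == "M1"]
  cc <- cor(t(k1[m1, ]))
  expect_gt(mean(cc[upper.tri(cc)]), 0.2)
})

test_that("background gene responses are uncorrelated on average", {
  d <- generate_dataset(small_params(17))
  bg <- names(d$truth$gene_module)[d$truth$gene_module == "background"][1:2]
  rs <- vapply(1:100, function(s) {
    k <- generate_knockdown_matrix(d$truth, n_regulators = 40, seed = s)
    cor(k[bg[1], ], k[bg[2], ])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("recovery scoring behaves at its boundaries and in expectation", {
  d <- generate_dataset(small_params(19))
  probes <- names(d$truth$probe_gene)
  bridges <- names(d$truth$gene_module)[d$truth$gene_module == "bridge"]
  bridge_probes <- probes[d$truth$probe_gene %in% bridges]

  mk <- function(flagged) {
    data.frame(node = probes, betweenness = as.numeric(probes %in% flagged),
               rank = seq_along(probes), is_bottleneck = probes %in% flagged)
  }
  perfect <- evaluate_recovery(mk(bridge_probes), d$truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)

  none <- evaluate_recovery(mk(character(0)), d$truth)
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))

  expect_error(
    evaluate_recovery(data.frame(node = "x", betweenness = 1, rank = 1L,
                                 is_bottleneck = TRUE), d$truth),
    "disjoint")

  # random flagging at fraction f recovers bridges at rate ~ f
  set.seed(23)
  f <- 0.3
  recalls <- vapply(1:50, function(i) {
    evaluate_recovery(mk(sample(probes, round(f * length(probes)))), d$truth)$recall
  }, numeric(1))
  se <- sqrt(f * (1 - f) / (length(bridges) * 50))
  expect_lt(abs(mean(recalls) - f), 4 * se)
})

test_that("with zero amplitude the differential filter stays near its size", {
  frac <- vapply(1:20, function(s) {
    d <- generate_dataset(small_params(s, amplitude = 0))
    mean(select_differential(d$expression, d$design)$selected)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("parameter validation rejects inconsistent settings", {
  expect_error(synthetic_params(n_modules = 1, n_bridge_genes = 2), "2 modules")
  expect_error(synthetic_params(noise_sd = 0), "noise_sd")
  expect_error(synthetic_params(duplicate_probe_fraction = 1.5), "\\[0, 1\\]")
  expect_error(synthetic_params(replicates = 0), "non-negative")
  bad_mix <- list(setNames(c(0.7, 0.7), c("M1", "M2")))
  expect_error(synthetic_params(n_bridge_genes = 1, bridge_mixing = bad_mix),
               "summing to 1")
})
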