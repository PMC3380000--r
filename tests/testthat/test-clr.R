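test_that("MI is symmetric to numerical tolerance", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(60)
    y <- 0.5 * x + rnorm(60)
    expect_equal(mutual_information(x, y), mutual_information(y, x),
                 tolerance = 1e-12)
  }
})

test_that("hard binning (order 1) reproduces the plug-in discrete MI", {
  set.seed(2)
  for (i in 1:10) {
    x <- rbinom(20, 1, 0.5)
    y <- rbinom(20, 1, 0.5)
    expect_equal(mutual_information(x, y, bins = 10, spline_order = 1),
                 max(discrete_mi(x, y), 0), tolerance = 1e-12)
  }
})

test_that("self-MI with hard binning equals the marginal entropy and is maximal", {
  set.seed(4)
  x <- rnorm(50)
  w <- bottlenet:::spline_bin_weights(x, 10, 1)
  p <- colMeans(w)
  h <- -sum(p[p > 0] * log(p[p > 0]))
  expect_equal(mutual_information(x, x, spline_order = 1), h, tolerance = 1e-12)
  for (i in 1:5) {
    y <- rnorm(50)
    expect_lte(mutual_information(x, y, spline_order = 1), h + 1e-12)
  }
  # smooth binning: self-MI still dominates MI with anything else
  expect_gt(mutual_information(x, x),
            mutual_information(x, 0.9 * x + rnorm(50, sd = 0.5)))
})

test_that("constant vectors carry zero information, with a warning", {
  expect_warning(mi <- mutual_information(rep(1, 20), rnorm(20)), "constant")
  expect_identical(mi, 0)
})

test_that("MI decreases as independent noise is added (data-processing sanity)", {
  sds <- c(0.1, 0.5, 1, 2, 4)
  acc <- matrix(0, 50, length(sds))
  set.seed(31)
  for (s in 1:50) {
    x <- rnorm(100)
    acc[s, ] <- vapply(sds, function(sd) {
      mutual_information(x, x + rnorm(100, sd = sd))
    }, numeric(1))
  }
  expect_true(all(diff(colMeans(acc)) < 0))
})

test_that("the 3-probe CLR toy example gives z(A,B) = 1.0000", {
  mi <- matrix(c(NA, 0.8, 0.2,
                 0.8, NA, 0.2,
                 0.2, 0.2, NA), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  # row C has no MI dispersion; its zero contribution is warned about
  expect_warning(z <- clr_scores(mi), "zero MI dispersion")
  expect_equal(round(z["A", "B"], 4), 1.0000)
  expect_equal(z, t(z))
})

test_that("uniform MI backgrounds give all-zero CLR scores", {
  mi <- matrix(0.3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(mi) <- NA
  expect_warning(z <- clr_scores(mi), "zero MI dispersion")
  expect_true(all(z == 0))
})

test_that("a pair's CLR score strictly increases with its MI, others fixed", {
  base <- matrix(0.2, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  base[1, 3] <- base[3, 1] <- 0.35
  base[2, 4] <- base[4, 2] <- 0.3
  prev <- -Inf
  for (v in seq(0.3, 0.9, by = 0.1)) {
    mi <- base
    mi[1, 2] <- mi[2, 1] <- v
    diag(mi) <- NA
    cur <- suppressWarnings(clr_scores(mi))[1, 2]
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("thresholding keeps qualifying edges and drops isolated nodes", {
  set.seed(8)
  x <- matrix(abs(rnorm(36)), 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  clr <- (x + t(x)) / 2
  diag(clr) <- 0

  full <- threshold_network(clr, 0)
  expect_equal(igraph::vcount(full), 6)
  expect_equal(igraph::ecount(full), 15)  # all positive scores kept

  empty <- threshold_network(clr, max(clr) + 1)
  expect_equal(igraph::vcount(empty), 0)

  mid <- threshold_network(clr, median(clr[upper.tri(clr)]))
  expect_true(all(igraph::E(mid)$clr_z >= igraph::graph_attr(mid, "threshold")))
  expect_true(all(igraph::degree(mid) >= 1))

  # monotone nesting of edge sets
  lo <- threshold_network(clr, 0.5)
  hi <- threshold_network(clr, 1.0)
  eset <- function(g) apply(igraph::as_edgelist(g), 1L,
                            function(r) paste(sort(r), collapse = "|"))
  expect_true(all(eset(hi) %in% eset(lo)))
})

test_that("threshold selection matches a brute-force scan of the grid", {
  set.seed(12)
  grid <- seq(0.2, 3, by = 0.2)
  for (i in 1:10) {
    x <- matrix(abs(rnorm(100)), 10, 10,
                dimnames = list(letters[1:10], letters[1:10]))
    clr <- (x + t(x)) / 2
    diag(clr) <- 0
    target <- sample(0:10, 1)
    got <- select_threshold_for_node_count(clr, target, grid)
    counts <- vapply(grid, function(z) {
      a <- clr >= z & clr > 0
      diag(a) <- FALSE
      sum(rowSums(a) > 0)
    }, numeric(1))
    expect_equal(abs(counts[grid == got] - target), min(abs(counts - target)))
  }
})

test_that("threshold selection honors its boundary and exact-hit contracts", {
  clr <- matrix(c(0, 2, 0.5, 2, 0, 0.1, 0.5, 0.1, 0), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  grid <- c(0.05, 0.3, 1, 3)
  # target above the total probe count: the smallest grid threshold
  expect_equal(select_threshold_for_node_count(clr, 10, grid), 0.05)
  # an exact hit is returned (2 nodes at z = 1)
  expect_equal(select_threshold_for_node_count(clr, 2, grid), 1)
  expect_error(select_threshold_for_node_count(clr, 2, numeric(0)), "non-empty")
})

test_that("networks export as edge-list TSV and GraphML", {
  clr <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  net <- threshold_network(clr, 1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_edge_list(net, tsv)
  el <- read.delim(tsv)
  expect_identical(colnames(el), c("probe_a", "probe_b", "clr_z"))
  write_network_graphml(net, gml)
  expect_true(any(grepl("graphml", readLines(gml, n = 3))))
})
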