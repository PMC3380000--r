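#' B-spline fractional bin-membership weights
#'
#' Implements the fractional binning behind the mutual-information
#' estimator: each observation is min-max rescaled onto
#' `[0, bins - spline_order + 1]` and weighted across the `bins` bins by
#' B-spline basis functions of the given order (order = degree + 1, so
#' order 3 is the quadratic basis; order 1 recovers ordinary hard
#' binning). The knot vector is `spline_order` copies of 0, the interior
#' integers, and `spline_order` copies of the upper bound, so each row of
#' weights sums to 1.
#'
#' @param x Numeric vector.
#' @param bins Number of bins (default 10).
#' @param spline_order B-spline order (default 3).
#' @return `length(x)` x `bins` weight matrix, or `NULL` when `x` is
#'   constant (zero range: no binning is defined).
#' @keywords internal
spline_bin_weights <- function(x, bins = 10L, spline_order = 3L) {
  stopifnot(bins >= spline_order, spline_order >= 1L)
  rng <- range(x)
  if (diff(rng) == 0) return(NULL)
  upper <- bins - spline_order + 1
  u <- (x - rng[1L]) / diff(rng) * upper
  u <- pmin(u, upper * (1 - 1e-12))  # right edge belongs to the last bin
  knots <- c(rep(0, spline_order), seq_len(bins - spline_order),
             rep(upper, spline_order))
  splines::splineDesign(knots, u, ord = spline_order)
}

# MI in nats from two weight matrices (columns = bins, rows = samples).
mi_from_weights <- function(wx, wy) {
  n <- nrow(wx)
  pxy <- crossprod(wx, wy) / n
  px <- colMeans(wx)
  py <- colMeans(wy)
  keep <- pxy > 0
  mi <- sum(pxy[keep] * log(pxy[keep] / outer(px, py)[keep]))
  max(mi, 0)
}

#' Mutual information between two expression profiles
#'
#' B-spline estimator of mutual information in nats: fractional bin
#' membership (see [spline_bin_weights()]), weighted joint and marginal
#' histograms normalized to probabilities, then
#' `MI = sum p(a,b) ln(p(a,b) / (p(a) p(b)))` over occupied cells, clamped
#' to be non-negative. A constant input vector has no information content
#' and yields 0 with a warning.
#'
#' @param x,y Numeric vectors of equal length, at least `spline_order + 1`.
#' @param bins Number of bins (default 10).
#' @param spline_order B-spline order (default 3; 1 = hard binning).
#' @return Scalar MI estimate in nats, `>= 0`.
#' @export
mutual_information <- function(x, y, bins = 10L, spline_order = 3L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < spline_order + 1L) {
    stop("need at least spline_order + 1 observations")
  }
  wx <- spline_bin_weights(x, bins, spline_order)
  wy <- spline_bin_weights(y, bins, spline_order)
  if (is.null(wx) || is.null(wy)) {
    warning("constant vector: mutual information defined as 0")
    return(0)
  }
  mi_from_weights(wx, wy)
}

#' All-pairs mutual-information matrix
#'
#' @param mat Expression matrix (probes x samples).
#' @param bins,spline_order Passed to the MI estimator.
#' @return Symmetric probes x probes matrix of MI values (nats), diagonal
#'   `NA` (self-MI is not used by CLR scoring).
#' @export
mi_matrix <- function(mat, bins = 10L, spline_order = 3L) {
  n <- nrow(mat)
  probes <- rownames(mat)
  W <- vector("list", n)
  n_const <- 0L
  for (i in seq_len(n)) {
    W[[i]] <- spline_bin_weights(mat[i, ], bins, spline_order)
    if (is.null(W[[i]])) n_const <- n_const + 1L
  }
  if (n_const > 0L) {
    warning(sprintf("%d constant probe profile(s): their MI set to 0", n_const))
  }
  mi <- matrix(0, n, n, dimnames = list(probes, probes))
  for (i in seq_len(n - 1L)) {
    if (is.null(W[[i]])) next
    for (j in seq.int(i + 1L, n)) {
      if (is.null(W[[j]])) next
      mi[i, j] <- mi[j, i] <- mi_from_weights(W[[i]], W[[j]])
    }
  }
  diag(mi) <- NA_real_
  mi
}

#' CLR background-corrected Z-scores
#'
#' For each pair (i, j) the MI value is standardized against the MI
#' background of each endpoint: `z_i = (MI(i,j) - mean_i) / sd_i` with the
#' mean and sample (n-1) standard deviation of row i's off-diagonal MI
#' values, and the pair score is
#' `z[i,j] = sqrt(max(0, z_i)^2 + max(0, z_j)^2)`. A row with zero MI
#' dispersion contributes 0 for all its pairs.
#'
#' @param mi Symmetric MI matrix from [mi_matrix()] (diagonal ignored).
#' @return Symmetric non-negative matrix of CLR Z-scores, diagonal 0.
#' @export
clr_scores <- function(mi) {
  n <- nrow(mi)
  if (n < 3L) stop("CLR row statistics need at least 3 probes")
  m <- mi
  diag(m) <- NA_real_
  row_mean <- rowMeans(m, na.rm = TRUE)
  row_sd <- apply(m, 1L, stats::sd, na.rm = TRUE)
  zero_sd <- row_sd == 0 | !is.finite(row_sd)
  if (any(zero_sd)) {
    warning(sprintf("%d probe row(s) with zero MI dispersion: their z contribution set to 0",
                    sum(zero_sd)))
    row_sd[zero_sd] <- Inf  # (x - mean)/Inf == 0
  }
  zi <- (m - row_mean) / row_sd
  zi <- pmax(zi, 0)
  z <- sqrt(zi^2 + t(zi)^2)
  diag(z) <- 0
  z
}

#' Threshold a CLR matrix into a coexpression network
#'
#' Retains edges with `z >= z_min`; probes left without any retained edge
#' are dropped from the network (they are "not considered"), and the
#' threshold is recorded as a graph attribute.
#'
#' @param clr CLR Z-score matrix from [clr_scores()].
#' @param z_min Minimum Z-score for an edge (>= 0).
#' @return Undirected `igraph` graph with edge attribute `clr_z` and graph
#'   attribute `threshold`; possibly empty.
#' @export
threshold_network <- function(clr, z_min) {
  stopifnot(z_min >= 0)
  idx <- which(upper.tri(clr) & clr >= z_min & clr > 0, arr.ind = TRUE)
  probes <- rownames(clr)
  if (nrow(idx) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    edges <- data.frame(from = probes[idx[, 1L]],
                        to = probes[idx[, 2L]],
                        clr_z = clr[idx],
                        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  }
  g <- igraph::set_graph_attr(g, "threshold", z_min)
  g
}

#' Choose the Z threshold that best matches a target node count
#'
#' Scans a grid of candidate thresholds and returns the one whose
#' thresholded network has a node count closest to `target_nodes` (nodes =
#' probes with at least one retained edge). Ties go to the larger, more
#' conservative threshold. This is how networks from different datasets
#' are brought to comparable size before bottleneck comparison.
#'
#' @param clr CLR Z-score matrix.
#' @param target_nodes Desired number of network nodes.
#' @param z_grid Ordered numeric vector of candidate thresholds.
#' @return The selected threshold (an element of `z_grid`).
#' @export
select_threshold_for_node_count <- function(clr, target_nodes,
                                            z_grid = seq(1, 10, by = 0.25)) {
  if (length(z_grid) == 0L) stop("z_grid must be non-empty")
  counts <- vapply(z_grid, function(z) {
    a <- clr >= z
    diag(a) <- FALSE
    sum(rowSums(a) > 0L)
  }, numeric(1L))
  d <- abs(counts - target_nodes)
  cand <- z_grid[d == min(d)]
  if (max(counts) < target_nodes) {
    # the target is unreachable: every threshold undershoots, so the tied
    # candidates all sit at the maximum (densest) node count — return the
    # smallest, which loses no nodes unnecessarily
    min(cand)
  } else {
    # ties around the target are broken toward the larger, more
    # conservative threshold
    max(cand)
  }
}

#' Write a network edge list as TSV
#' @param net Coexpression network (`igraph`).
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  colnames(el)[1:2] <- c("probe_a", "probe_b")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network as GraphML (Cytoscape-compatible)
#' @param net `igraph` graph.
#' @param path Output path.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
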