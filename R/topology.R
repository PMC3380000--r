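#' Betweenness centrality of every network node
#'
#' Unnormalized betweenness in the pair-count convention: for node v, the
#' sum over unordered pairs s != t != v of the fraction of s-t shortest
#' paths passing through v. Paths are counted on the unweighted (hop
#' metric) graph — CLR edge weights play no role in path length — and
#' pairs in different components contribute 0.
#'
#' @param net Coexpression network (`igraph`).
#' @return Named numeric vector of betweenness scores.
#' @export
node_betweenness <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  igraph::betweenness(net, directed = FALSE, weights = NA)
}

#' Rank nodes by betweenness and flag the top fraction as bottlenecks
#'
#' Nodes are sorted by descending betweenness (ties broken by lexicographic
#' node id, so the ranking is deterministic) and the top
#' `ceiling(fraction * N)` are flagged as bottlenecks.
#'
#' @param b Named numeric vector from [node_betweenness()].
#' @param fraction Fraction of nodes to flag, in (0, 1\] (default 0.2).
#' @return `data.frame` with columns `node`, `betweenness`, `rank`
#'   (1 = highest), `is_bottleneck`.
#' @export
rank_bottlenecks <- function(b, fraction = 0.2) {
  if (length(b) == 0L) stop("empty betweenness vector")
  stopifnot(fraction > 0, fraction <= 1)
  ord <- order(-b, names(b), method = "radix")
  n_flag <- ceiling(fraction * length(b))
  data.frame(
    node = names(b)[ord],
    betweenness = unname(b[ord]),
    rank = seq_along(b),
    is_bottleneck = seq_along(b) <= n_flag,
    stringsAsFactors = FALSE
  )
}

#' k-th order neighborhood of a node
#'
#' All nodes within hop distance 1..`order` of `node`, excluding the node
#' itself. Order 1 is the first-order (direct-neighbor) network, order 2
#' the second-order network.
#'
#' @param net Coexpression network (`igraph`).
#' @param node Node id.
#' @param order Maximum hop distance (integer >= 1).
#' @return Character vector of node ids.
#' @export
neighborhood_nodes <- function(net, node, order = 1L) {
  if (!node %in% igraph::V(net)$name) {
    stop(sprintf("node '%s' is not in the network", node))
  }
  stopifnot(order >= 1L)
  nb <- igraph::ego(net, order = order, nodes = node, mindist = 1L)[[1L]]
  nb$name
}

#' Write a bottleneck ranking as TSV
#' @param ranking Data frame from [rank_bottlenecks()].
#' @param path Output path.
#' @export
write_bottlenecks <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
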