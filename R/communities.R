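#' Louvain community partition of a network
#'
#' Two-phase greedy modularity optimization (local moves, then aggregation,
#' repeated until no gain). The node visit order is randomized, so the
#' partition is a function of the seed; the same seed always returns the
#' same partition. By default the thresholded graph is treated as
#' unweighted, matching the betweenness convention; set `weighted = TRUE`
#' to optimize weighted modularity over the CLR scores.
#'
#' @param net Coexpression network (`igraph`).
#' @param seed Integer RNG seed.
#' @param weighted Use `clr_z` edge weights in modularity (default FALSE).
#' @return List with `membership` (named integer vector, cluster ids) and
#'   `modularity` (Q of the returned partition).
#' @export
louvain_partition <- function(net, seed, weighted = FALSE) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  w <- if (weighted) igraph::E(net)$clr_z else NA
  set.seed(seed)
  cl <- igraph::cluster_louvain(net, weights = w)
  mem <- igraph::membership(cl)
  list(
    membership = stats::setNames(as.integer(mem), names(mem)),
    modularity = igraph::modularity(net, mem, weights = if (weighted) w else NULL)
  )
}

#' Hypergeometric gene-set enrichment of one cluster
#'
#' Upper-tail hypergeometric test of each term against the cluster:
#' population N = background genes (the gene symbols of the network under
#' study, not the whole array), successes K = term members in the
#' background, draws n = cluster genes, observed k = cluster-term overlap;
#' p = P(X >= k). BH-adjusted p-values across the supplied terms are
#' reported alongside; the cluster label uses the smallest raw p.
#'
#' @param cluster_genes Character vector of gene symbols (intersected with
#'   the background).
#' @param terms Gene-set collection ([read_gene_sets()]).
#' @param background Character vector: the gene universe.
#' @return `data.frame` sorted by `p_hyper` with columns `term_id`,
#'   `term_name`, `k`, `K`, `n`, `N`, `p_hyper`, `p_adjusted`; the first
#'   row is the best term.
#' @export
hypergeometric_enrichment <- function(cluster_genes, terms, background) {
  background <- unique(background[nzchar(background)])
  if (length(background) == 0L) stop("empty background gene universe")
  cluster_genes <- intersect(unique(cluster_genes), background)
  N <- length(background)
  n <- length(cluster_genes)
  desc <- attr(terms, "descriptions")
  res <- data.frame(
    term_id = names(terms),
    term_name = if (is.null(desc)) names(terms) else unname(desc[names(terms)]),
    stringsAsFactors = FALSE
  )
  res$K <- vapply(terms, function(m) length(intersect(m, background)), integer(1L))
  res$k <- vapply(terms, function(m) length(intersect(m, cluster_genes)), integer(1L))
  res$n <- n
  res$N <- N
  res$p_hyper <- stats::phyper(res$k - 1L, res$K, N - res$K, n, lower.tail = FALSE)
  res$p_adjusted <- adjust_pvalues(res$p_hyper)
  res <- res[order(res$p_hyper, res$term_id), ]
  rownames(res) <- NULL
  res[, c("term_id", "term_name", "k", "K", "n", "N", "p_hyper", "p_adjusted")]
}

#' Enrichment of all large clusters in a partition
#'
#' Runs [hypergeometric_enrichment()] for every cluster with at least
#' `min_cluster_size` member probes, with the background fixed to the gene
#' symbols of all network nodes. Unannotated probes (empty symbol) count
#' toward cluster size but are excluded from the gene-level test.
#'
#' @param partition List from [louvain_partition()].
#' @param annot Probe annotation (named character vector).
#' @param terms Gene-set collection.
#' @param min_cluster_size Minimum cluster membership in probes (default 10).
#' @return Named list (cluster id -> enrichment data frame).
#' @export
enrich_clusters <- function(partition, annot, terms, min_cluster_size = 10L) {
  mem <- partition$membership
  background <- probe_genes(annot, names(mem))
  sizes <- table(mem)
  big <- names(sizes)[sizes >= min_cluster_size]
  res <- lapply(big, function(cl) {
    genes <- probe_genes(annot, names(mem)[mem == as.integer(cl)])
    hypergeometric_enrichment(genes[nzchar(genes)], terms, background)
  })
  stats::setNames(res, big)
}

#' Condensed bottleneck-cluster graph
#'
#' Summarizes a network as bottleneck nodes (circles) connected to large
#' community nodes (squares). Clusters with at least `min_cluster_size`
#' probes appear as square nodes labeled with their best enriched term and
#' `ceiling(-log10 p)`; every bottleneck gets a `membership` edge to its
#' own cluster (when shown) and a `linkage` edge to every other shown
#' cluster that contains at least one of its direct network neighbors.
#'
#' @param net Coexpression network.
#' @param partition List from [louvain_partition()].
#' @param ranking Bottleneck ranking from [rank_bottlenecks()].
#' @param enrich Named list from [enrich_clusters()] (may be `NULL`; shown
#'   clusters are then labeled by id only).
#' @param min_cluster_size Minimum probes for a cluster node (default 10).
#' @param annot Optional probe annotation used to label bottleneck nodes by
#'   gene symbol.
#' @return `igraph` graph with node attributes `node_type` ("bottleneck" /
#'   "cluster"), `shape`, `size`, `label`, `neg_log10_p`, and edge
#'   attribute `edge_type` ("membership" / "linkage").
#' @export
condense <- function(net, partition, ranking, enrich = NULL,
                     min_cluster_size = 10L, annot = NULL) {
  mem <- partition$membership
  sizes <- table(mem)
  shown <- as.integer(names(sizes)[sizes >= min_cluster_size])
  bn <- ranking$node[ranking$is_bottleneck]

  cluster_vid <- function(cl) sprintf("cluster_%d", cl)
  nlp <- rep(NA_real_, length(shown))
  clab <- character(length(shown))
  for (i in seq_along(shown)) {
    cl <- as.character(shown[i])
    if (!is.null(enrich) && cl %in% names(enrich) && nrow(enrich[[cl]]) > 0L) {
      best <- enrich[[cl]][1L, ]
      nlp[i] <- -log10(best$p_hyper)
      clab[i] <- sprintf("%s %d", best$term_name, ceiling(-log10(best$p_hyper)))
    } else {
      clab[i] <- cluster_vid(shown[i])
    }
  }

  bn_label <- bn
  if (!is.null(annot)) {
    g <- probe_genes(annot, bn)
    bn_label <- ifelse(nzchar(g), g, bn)
  }

  nodes <- data.frame(
    name = c(bn, cluster_vid(shown)),
    node_type = c(rep("bottleneck", length(bn)), rep("cluster", length(shown))),
    shape = c(rep("circle", length(bn)), rep("square", length(shown))),
    size = c(rep(1L, length(bn)), as.integer(sizes[as.character(shown)])),
    label = c(bn_label, clab),
    neg_log10_p = c(rep(NA_real_, length(bn)), unname(nlp)),
    stringsAsFactors = FALSE
  )

  edges <- list()
  for (b in bn) {
    own <- mem[[b]]
    if (own %in% shown) {
      edges[[length(edges) + 1L]] <-
        data.frame(from = b, to = cluster_vid(own), edge_type = "membership")
    }
    nb <- neighborhood_nodes(net, b, 1L)
    nb_cl <- unique(mem[nb])
    for (cl in setdiff(intersect(nb_cl, shown), own)) {
      edges[[length(edges) + 1L]] <-
        data.frame(from = b, to = cluster_vid(cl), edge_type = "linkage")
    }
  }
  edf <- if (length(edges) > 0L) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), edge_type = character(0))
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = nodes)
}

#' Write per-cluster enrichment tables as one TSV
#' @param enrich Named list from [enrich_clusters()].
#' @param path Output path.
#' @export
write_enrichment <- function(enrich, path) {
  rows <- lapply(names(enrich), function(cl) {
    cbind(cluster_id = cl, enrich[[cl]])
  })
  df <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(cluster_id = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
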