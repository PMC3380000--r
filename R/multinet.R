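#' Gene-level bottleneck set of one network
#'
#' Maps bottleneck-flagged probesets to gene symbols. A gene is a
#' bottleneck gene when at least one of its probesets is flagged;
#' unannotated probes are dropped (with a message reporting how many).
#'
#' @param ranking Bottleneck ranking from [rank_bottlenecks()].
#' @param annot Probe annotation (named character vector); every ranked
#'   probe must be present.
#' @return Character vector of unique gene symbols.
#' @export
bottleneck_genes <- function(ranking, annot) {
  flagged <- ranking$node[ranking$is_bottleneck]
  genes <- probe_genes(annot, flagged)
  n_drop <- sum(!nzchar(genes))
  if (n_drop > 0L) {
    message(sprintf("dropping %d unannotated bottleneck probe(s)", n_drop))
  }
  sort(unique(genes[nzchar(genes)]))
}

#' Conserved bottlenecks across networks
#'
#' @param sets List of two or more gene-symbol vectors.
#' @return Their exact intersection.
#' @export
conserved_bottlenecks <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 bottleneck sets")
  sort(Reduce(intersect, sets))
}

#' Permutation p-value for a multi-network gene-set overlap
#'
#' Null model: for each network, a uniformly random gene subset of the same
#' size as its bottleneck set is drawn from that network's own gene
#' universe; the draws are intersected and the overlap counted. The
#' add-one estimator `p = (1 + #{perm >= observed}) / (n_permutations + 1)`
#' is returned, so p is never 0 and never below
#' `1/(n_permutations + 1)`.
#'
#' @param universes List of per-network gene universes (character vectors).
#' @param set_sizes Integer vector, one subset size per network.
#' @param observed Observed overlap count (integer >= 0).
#' @param n_permutations Number of random draws (default 1e5).
#' @param seed Integer RNG seed.
#' @return Scalar permutation p-value.
#' @export
overlap_pvalue <- function(universes, set_sizes, observed,
                           n_permutations = 100000L, seed = 1L) {
  stopifnot(length(universes) == length(set_sizes), length(universes) >= 2L)
  if (observed < 0) stop("observed overlap must be >= 0")
  if (any(set_sizes > lengths(universes))) {
    stop("set size exceeds universe size")
  }
  if (observed == 0L) return(1)
  # integer encoding over the union for fast intersection counting
  all_genes <- unique(unlist(universes))
  uni_idx <- lapply(universes, function(u) match(unique(u), all_genes))
  set.seed(seed)
  m <- length(all_genes)
  hits <- 0L
  tab <- integer(m)
  k <- length(universes)
  for (p in seq_len(n_permutations)) {
    tab[] <- 0L
    for (i in seq_len(k)) {
      drawn <- uni_idx[[i]][sample.int(length(uni_idx[[i]]), set_sizes[i])]
      tab[drawn] <- tab[drawn] + 1L
    }
    if (sum(tab == k) >= observed) hits <- hits + 1L
  }
  (1 + hits) / (n_permutations + 1)
}

#' Conserved-bottleneck report across networks
#'
#' Intersects per-network bottleneck gene sets and attaches the permutation
#' significance of the overlap under each network's own universe and set
#' size.
#'
#' @param bottleneck_sets Named list of per-network bottleneck gene sets.
#' @param universes Named list of per-network gene universes (genes of all
#'   network nodes).
#' @param n_permutations,seed Passed to [overlap_pvalue()].
#' @return List: `network_names`, `set_sizes`, `intersection`,
#'   `observed_overlap`, `p_perm`, `n_permutations`, `seed`.
#' @export
conserved_report <- function(bottleneck_sets, universes,
                             n_permutations = 100000L, seed = 1L) {
  stopifnot(identical(names(bottleneck_sets), names(universes)))
  inter <- conserved_bottlenecks(bottleneck_sets)
  p <- overlap_pvalue(universes, lengths(bottleneck_sets), length(inter),
                      n_permutations = n_permutations, seed = seed)
  list(
    network_names = names(bottleneck_sets),
    set_sizes = unname(lengths(bottleneck_sets)),
    intersection = inter,
    observed_overlap = length(inter),
    p_perm = p,
    n_permutations = n_permutations,
    seed = seed
  )
}

#' Shared-neighbor table of a focal gene across networks
#'
#' For each network, the first-order neighborhood is the union of the
#' direct neighbors of every probeset of the focal gene present in that
#' network; genes reached only at hop 2 get order code 2. Rows are sorted
#' by the number of networks where the gene is a first-order neighbor
#' (descending), then by symbol. The focal gene itself and unannotated
#' neighbors are excluded.
#'
#' @param nets Named list of coexpression networks (`igraph`).
#' @param annot Probe annotation covering all network nodes.
#' @param focal_gene Gene symbol; must have a probe node in >= 1 network.
#' @param max_order 1 (direct neighbors only) or 2 (default).
#' @return `data.frame` with column `gene` and one order-code column per
#'   network (1, 2, or NA).
#' @export
shared_neighbor_table <- function(nets, annot, focal_gene, max_order = 2L) {
  stopifnot(max_order >= 1L)
  focal_probes <- names(annot)[annot == focal_gene]
  codes <- lapply(nets, function(net) {
    present <- intersect(focal_probes, igraph::V(net)$name)
    if (length(present) == 0L) return(stats::setNames(integer(0), character(0)))
    nb1 <- unique(unlist(lapply(present, neighborhood_nodes, net = net, order = 1L)))
    nb1 <- setdiff(nb1, focal_probes)
    g1 <- unique(probe_genes(annot, nb1))
    g1 <- setdiff(g1[nzchar(g1)], focal_gene)
    out <- stats::setNames(rep(1L, length(g1)), g1)
    if (max_order >= 2L) {
      nb2 <- unique(unlist(lapply(present, neighborhood_nodes, net = net,
                                  order = max_order)))
      nb2 <- setdiff(nb2, c(nb1, focal_probes))
      g2 <- unique(probe_genes(annot, nb2))
      g2 <- setdiff(g2[nzchar(g2)], c(focal_gene, g1))
      out <- c(out, stats::setNames(rep(2L, length(g2)), g2))
    }
    out
  })
  if (all(lengths(codes) == 0L)) {
    stop(sprintf("gene '%s' has no probe node in any network", focal_gene))
  }
  genes <- sort(unique(unlist(lapply(codes, names))))
  tab <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nm in names(nets)) {
    tab[[nm]] <- unname(codes[[nm]][genes])
  }
  n_first <- rowSums(as.matrix(tab[, names(nets), drop = FALSE]) == 1L,
                     na.rm = TRUE)
  tab <- tab[order(-n_first, tab$gene), ]
  rownames(tab) <- NULL
  attr(tab, "focal_gene") <- focal_gene
  tab
}
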