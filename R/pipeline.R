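#' Run the full single-dataset pipeline
#'
#' Differential filtering -> MI matrix -> CLR scores -> thresholded
#' network (fixed `z_threshold`, or chosen by node-count matching when
#' `target_nodes` is given) -> betweenness bottlenecks -> Louvain
#' communities (+ optional gene-set enrichment) -> condensed
#' bottleneck-cluster graph. All stage outputs are written under
#' `out_dir` along with a JSON run manifest recording parameters and
#' per-stage row counts (including how many probes lost all edges at the
#' threshold).
#'
#' @param expression Probes x samples log2 matrix.
#' @param design Sample-design data frame.
#' @param annotation Probe annotation (named character vector).
#' @param out_dir Output directory (created if needed); `NULL` to skip all
#'   file output.
#' @param label Dataset label used in the manifest.
#' @param z_threshold Fixed CLR Z threshold (e.g. 5.0); exactly one of
#'   `z_threshold` / `target_nodes` must be given.
#' @param target_nodes Desired node count; the threshold is then selected
#'   from `z_grid` by [select_threshold_for_node_count()].
#' @param z_grid Candidate thresholds for node-count matching.
#' @param bottleneck_fraction Top betweenness fraction flagged (default 0.2).
#' @param min_cluster_size Minimum probes per enriched/condensed cluster
#'   (default 10).
#' @param alpha,fc_threshold Differential-selection cutoffs (defaults 0.05
#'   and 2.0).
#' @param gene_sets Optional gene-set collection for cluster enrichment.
#' @param bins,spline_order MI estimator settings (defaults 10 and 3).
#' @param seed Seed for the Louvain visit order.
#' @return List: `diffexpr`, `network`, `threshold`, `ranking`,
#'   `partition`, `enrichment`, `condensed`, `manifest`.
#' @export
run_dataset <- function(expression, design, annotation, out_dir = NULL,
                        label = "dataset", z_threshold = NULL,
                        target_nodes = NULL, z_grid = seq(1, 10, by = 0.25),
                        bottleneck_fraction = 0.2, min_cluster_size = 10L,
                        alpha = 0.05, fc_threshold = 2.0, gene_sets = NULL,
                        bins = 10L, spline_order = 3L, seed = 1L) {
  if (is.null(z_threshold) == is.null(target_nodes)) {
    stop("give exactly one of z_threshold or target_nodes")
  }
  de <- select_differential(expression, design, alpha = alpha,
                            fc_threshold = fc_threshold)
  sel <- de$probe_id[de$selected]
  if (length(sel) < 3L) stop(sprintf("stage diffexpr: only %d probes selected", length(sel)))

  mi <- mi_matrix(expression[sel, , drop = FALSE], bins = bins,
                  spline_order = spline_order)
  clr <- clr_scores(mi)
  thr <- if (is.null(z_threshold)) {
    select_threshold_for_node_count(clr, target_nodes, z_grid)
  } else z_threshold
  net <- threshold_network(clr, thr)
  if (igraph::vcount(net) == 0L) stop("stage network: no edges survive the threshold")

  b <- node_betweenness(net)
  ranking <- rank_bottlenecks(b, fraction = bottleneck_fraction)
  partition <- louvain_partition(net, seed = seed)
  enrichment <- if (!is.null(gene_sets)) {
    enrich_clusters(partition, annotation, gene_sets, min_cluster_size)
  } else NULL
  condensed <- condense(net, partition, ranking, enrichment,
                        min_cluster_size, annot = annotation)

  manifest <- list(
    label = label,
    parameters = list(alpha = alpha, fc_threshold = fc_threshold,
                      bins = bins, spline_order = spline_order,
                      z_threshold = thr,
                      threshold_selected_by_node_count = is.null(z_threshold),
                      bottleneck_fraction = bottleneck_fraction,
                      min_cluster_size = min_cluster_size, seed = seed),
    counts = list(probes_total = nrow(expression),
                  probes_selected = length(sel),
                  probes_dropped_no_edges = length(sel) - igraph::vcount(net),
                  network_nodes = igraph::vcount(net),
                  network_edges = igraph::ecount(net),
                  bottlenecks = sum(ranking$is_bottleneck),
                  clusters = length(unique(partition$membership)),
                  clusters_enriched = length(enrichment))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(de, file.path(out_dir, "diffexpr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_edge_list(net, file.path(out_dir, "network_edges.tsv"))
    write_network_graphml(net, file.path(out_dir, "network.graphml"))
    write_bottlenecks(ranking, file.path(out_dir, "bottlenecks.tsv"))
    utils::write.table(
      data.frame(node = names(partition$membership),
                 cluster_id = unname(partition$membership)),
      file.path(out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (!is.null(enrichment)) {
      write_enrichment(enrichment, file.path(out_dir, "enrichment.tsv"))
    }
    write_network_graphml(condensed, file.path(out_dir, "condensed.graphml"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(diffexpr = de, network = net, threshold = thr, ranking = ranking,
       partition = partition, enrichment = enrichment, condensed = condensed,
       manifest = manifest)
}

#' Run the full multi-network benchmark study on synthetic data
#'
#' Generates a calibration dataset plus `n_datasets` evaluation datasets
#' that share their planted bridge genes, calibrates the CLR Z threshold
#' on the calibration dataset (F1 of edge recovery against the planted
#' truth, the same precision/recall balancing by which CLR thresholds are
#' chosen on known reference networks), runs the single-dataset pipeline
#' on every evaluation dataset — the dataset with the most selected probes
#' is the reference and carries the calibrated threshold; the others are
#' brought to approximately its node count by
#' [select_threshold_for_node_count()] — and finally intersects the
#' bottleneck gene sets across networks with permutation significance.
#'
#' @param seed Integer base seed; sub-seeds for the calibration and
#'   evaluation datasets are derived from it.
#' @param n_datasets Number of evaluation datasets (default 3).
#' @param params Template `synthetic_params`; its seed field is replaced
#'   per dataset.
#' @param n_permutations Draws for the overlap permutation test.
#' @param out_dir Optional output directory (per-dataset subdirectories
#'   plus a comparison directory).
#' @return List: `calibration`, `datasets`, `runs`, `recovery` (per-dataset
#'   precision/recall of planted-bridge recovery), `comparison`.
#' @export
run_synthetic_study <- function(seed, n_datasets = 3L,
                                params = synthetic_params(),
                                n_permutations = 100000L, out_dir = NULL) {
  stopifnot(n_datasets >= 2L)
  reseed <- function(s) { p <- params; p$seed <- as.integer(s); p }

  cal <- generate_dataset(reseed(seed + 17L))
  de_cal <- select_differential(cal$expression, cal$design)
  mi_cal <- mi_matrix(cal$expression[de_cal$probe_id[de_cal$selected], ,
                                     drop = FALSE])
  calibration <- calibrate_edge_threshold(clr_scores(mi_cal),
                                          cal$annotation, cal$truth)

  datasets <- lapply(seq_len(n_datasets),
                     function(i) generate_dataset(reseed(seed + i)))
  n_sel <- vapply(datasets, function(d) {
    sum(select_differential(d$expression, d$design)$selected)
  }, numeric(1L))
  ref <- which.max(n_sel)

  runs <- vector("list", n_datasets)
  names(runs) <- sprintf("net%d", seq_len(n_datasets))
  dir_for <- function(i) if (is.null(out_dir)) NULL else
    file.path(out_dir, names(runs)[i])
  runs[[ref]] <- run_dataset(
    datasets[[ref]]$expression, datasets[[ref]]$design,
    datasets[[ref]]$annotation, out_dir = dir_for(ref),
    label = names(runs)[ref], z_threshold = calibration$threshold,
    gene_sets = generate_gene_sets(datasets[[ref]]$truth),
    seed = seed + ref)
  target <- igraph::vcount(runs[[ref]]$network) + 1L
  for (i in setdiff(seq_len(n_datasets), ref)) {
    runs[[i]] <- run_dataset(
      datasets[[i]]$expression, datasets[[i]]$design,
      datasets[[i]]$annotation, out_dir = dir_for(i),
      label = names(runs)[i], target_nodes = target,
      gene_sets = generate_gene_sets(datasets[[i]]$truth),
      seed = seed + i)
  }

  recovery <- lapply(seq_len(n_datasets), function(i) {
    evaluate_recovery(runs[[i]]$ranking, datasets[[i]]$truth)
  })
  names(recovery) <- names(runs)

  comparison <- run_comparison(
    runs, datasets[[1L]]$annotation,
    out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, "comparison"),
    n_permutations = n_permutations, seed = seed)

  list(calibration = calibration, datasets = datasets, runs = runs,
       reference = ref, recovery = recovery, comparison = comparison)
}

#' Compare bottlenecks across completed dataset runs
#'
#' Intersects the gene-level bottleneck sets of two or more runs, attaches
#' the permutation significance of the overlap (null: random gene sets of
#' each network's own bottleneck-set size drawn from its own node-gene
#' universe), and builds shared-neighbor tables for the focal genes
#' (default: the conserved bottlenecks themselves).
#'
#' @param runs Named list of results from [run_dataset()] (>= 2).
#' @param annotation Probe annotation covering all networks' nodes.
#' @param out_dir Optional output directory for the report JSON and tables.
#' @param n_permutations,seed Passed to [overlap_pvalue()].
#' @param focal_genes Genes for shared-neighbor tables (default: the
#'   conserved bottleneck set).
#' @return List: `report` (see [conserved_report()]) and
#'   `neighborhood_tables` (one per focal gene).
#' @export
run_comparison <- function(runs, annotation, out_dir = NULL,
                           n_permutations = 100000L, seed = 1L,
                           focal_genes = NULL) {
  if (length(runs) < 2L) stop("need >= 2 completed dataset runs")
  if (is.null(names(runs)) || any(!nzchar(names(runs)))) {
    stop("runs must be a named list")
  }
  bn_sets <- lapply(runs, function(r) bottleneck_genes(r$ranking, annotation))
  universes <- lapply(runs, function(r) {
    g <- probe_genes(annotation, igraph::V(r$network)$name)
    sort(unique(g[nzchar(g)]))
  })
  report <- conserved_report(bn_sets, universes,
                             n_permutations = n_permutations, seed = seed)
  if (is.null(focal_genes)) focal_genes <- report$intersection
  nets <- lapply(runs, `[[`, "network")
  tables <- lapply(focal_genes, function(g) {
    shared_neighbor_table(nets, annotation, g)
  })
  names(tables) <- focal_genes

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "conserved_bottlenecks.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    bn_df <- do.call(rbind, lapply(names(bn_sets), function(nm) {
      data.frame(network = nm, gene = bn_sets[[nm]], stringsAsFactors = FALSE)
    }))
    utils::write.table(bn_df, file.path(out_dir, "bottleneck_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (g in names(tables)) {
      utils::write.table(tables[[g]],
                         file.path(out_dir, sprintf("neighbors_%s.tsv", g)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(report = report, neighborhood_tables = tables)
}
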