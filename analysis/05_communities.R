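# Functional condensation: Louvain communities on each network,
# hypergeometric enrichment of clusters with >= 10 probes against the
# module gene sets (background = genes of that network's nodes), and the
# condensed bottleneck-cluster graph with typed membership/linkage edges.

source("analysis/00_config.R")
suppressPackageStartupMessages(library(igraph))
data_dir <- file.path(RESULTS, "data")

for (i in seq_len(N_DATASETS)) {
  id <- DATASET_IDS[i]
  net <- read_graph(file.path(RESULTS, paste0(id, "_network.graphml")),
                    format = "graphml")
  annot <- read_probe_annotation(file.path(data_dir, paste0(id, "_annotation.tsv")))
  sets <- read_gene_sets(file.path(data_dir, paste0(id, "_gene_sets.gmt")))
  ranking <- utils::read.delim(file.path(RESULTS, paste0(id, "_bottlenecks.tsv")))

  part <- louvain_partition(net, seed = STUDY_SEED + i)
  enr <- enrich_clusters(part, annot, sets, min_cluster_size = 10L)
  write_enrichment(enr, file.path(RESULTS, paste0(id, "_enrichment.tsv")))
  cg <- condense(net, part, ranking, enr, min_cluster_size = 10L, annot = annot)
  write_network_graphml(cg, file.path(RESULTS, paste0(id, "_condensed.graphml")))

  best <- vapply(enr, function(e) sprintf("%s (p=%.1e)", e$term_id[1], e$p_hyper[1]),
                 character(1))
  cat(sprintf("%s: modularity %.3f, %d clusters >= 10 probes\n",
              id, part$modularity, length(enr)))
  for (cl in names(best)) cat(sprintf("  cluster %s -> %s\n", cl, best[[cl]]))
}
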