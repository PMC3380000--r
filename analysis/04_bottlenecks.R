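# Bottleneck identification: betweenness centrality on each thresholded
# network (unweighted shortest paths), nodes ranked, the top 20% flagged
# as bottlenecks, and recovery of the planted bridge genes scored.

source("analysis/00_config.R")
suppressPackageStartupMessages(library(igraph))

for (i in seq_len(N_DATASETS)) {
  id <- DATASET_IDS[i]
  net <- read_graph(file.path(RESULTS, paste0(id, "_network.graphml")),
                    format = "graphml")
  ranking <- rank_bottlenecks(node_betweenness(net), fraction = 0.2)
  write_bottlenecks(ranking, file.path(RESULTS, paste0(id, "_bottlenecks.tsv")))

  truth <- generate_dataset(dataset_params(i))$truth
  rec <- evaluate_recovery(ranking, truth)
  cat(sprintf("%s: %d bottlenecks flagged of %d nodes; planted-bridge recall %.2f, precision %.2f\n",
              id, sum(ranking$is_bottleneck), nrow(ranking),
              rec$recall, rec$precision))
}
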