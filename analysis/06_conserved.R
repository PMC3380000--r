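# Conserved bottlenecks: gene-level bottleneck sets of the three networks
# are intersected; significance of the overlap comes from a permutation
# null drawing random gene sets of each network's own bottleneck-set size
# from its own node-gene universe. Shared-neighbor tables are written for
# every conserved bottleneck gene.

source("analysis/00_config.R")
suppressPackageStartupMessages(library(igraph))
data_dir <- file.path(RESULTS, "data")

annot <- read_probe_annotation(file.path(data_dir, "net1_annotation.tsv"))
runs <- lapply(seq_len(N_DATASETS), function(i) {
  id <- DATASET_IDS[i]
  list(network = read_graph(file.path(RESULTS, paste0(id, "_network.graphml")),
                            format = "graphml"),
       ranking = utils::read.delim(file.path(RESULTS, paste0(id, "_bottlenecks.tsv"))))
})
names(runs) <- DATASET_IDS

cmp <- run_comparison(runs, annot, out_dir = file.path(RESULTS, "comparison"),
                      n_permutations = 100000L, seed = STUDY_SEED)
rep <- cmp$report
cat(sprintf("conserved bottlenecks across %d networks: %d genes (p_perm = %.3g over %d draws)\n",
            length(rep$network_names), rep$observed_overlap, rep$p_perm,
            rep$n_permutations))
truth <- generate_dataset(dataset_params(1L))$truth
bridges <- names(truth$gene_module)[truth$gene_module == "bridge"]
cat(sprintf("  of which planted bridges: %d of %d (%s)\n",
            length(intersect(rep$intersection, bridges)), length(bridges),
            paste(intersect(rep$intersection, bridges), collapse = ", ")))
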