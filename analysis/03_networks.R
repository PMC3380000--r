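# Coexpression network inference: B-spline mutual information (10 bins,
# order 3) over the selected probes, CLR background-corrected Z-scores,
# and thresholding. The CLR Z threshold is calibrated on the dedicated
# calibration dataset by the F1 of edge recovery against its planted
# truth (the same precision/recall balancing by which CLR thresholds are
# carried over from known reference networks); the dataset with the most
# selected probes is the reference network, and the other networks are
# brought to approximately its node count.

source("analysis/00_config.R")
suppressPackageStartupMessages(library(igraph))
data_dir <- file.path(RESULTS, "data")

clr_for <- function(id) {
  mat <- read_expression(file.path(data_dir, paste0(id, "_expression.tsv")))
  de <- utils::read.delim(file.path(RESULTS, paste0(id, "_diffexpr.tsv")))
  mi <- mi_matrix(mat[de$probe_id[de$selected], , drop = FALSE])
  clr_scores(mi)
}

cal_clr <- clr_for("calibration")
cal_truth <- generate_dataset(dataset_params(17L))$truth
cal_annot <- read_probe_annotation(file.path(data_dir, "calibration_annotation.tsv"))
calib <- calibrate_edge_threshold(cal_clr, cal_annot, cal_truth)
cat(sprintf("calibrated CLR Z threshold: %.2f (edge F1 %.3f, precision %.3f, recall %.3f)\n",
            calib$threshold, calib$f1, calib$precision, calib$recall))

clrs <- lapply(DATASET_IDS, clr_for)
names(clrs) <- DATASET_IDS
n_sel <- vapply(clrs, nrow, numeric(1))
ref <- which.max(n_sel)
cat(sprintf("reference network: %s (%d selected probes)\n",
            DATASET_IDS[ref], n_sel[ref]))

thresholds <- numeric(N_DATASETS)
thresholds[ref] <- calib$threshold
ref_net <- threshold_network(clrs[[ref]], calib$threshold)
for (i in setdiff(seq_len(N_DATASETS), ref)) {
  thresholds[i] <- select_threshold_for_node_count(
    clrs[[i]], vcount(ref_net) + 1L)
}

for (i in seq_len(N_DATASETS)) {
  id <- DATASET_IDS[i]
  net <- threshold_network(clrs[[i]], thresholds[i])
  write_edge_list(net, file.path(RESULTS, paste0(id, "_edges.tsv")))
  write_network_graphml(net, file.path(RESULTS, paste0(id, "_network.graphml")))
  cat(sprintf("%s: z >= %.2f, %d nodes, %d edges (%d probes dropped edgeless)\n",
              id, thresholds[i], vcount(net), ecount(net),
              as.integer(n_sel[i] - vcount(net))))
}
writeLines(sprintf("%s\t%g", DATASET_IDS, thresholds),
           file.path(RESULTS, "thresholds.tsv"))
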