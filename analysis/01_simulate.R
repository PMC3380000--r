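# Generate the synthetic study: three expression datasets that share their
# planted coexpression modules' gene names and bridge genes (each dataset
# redraws its own latent profiles and noise), plus one calibration dataset
# used only for threshold calibration. Writes the expression matrices,
# sample designs, probe annotations, module gene sets and the planted
# truth under results/analysis/data/.

source("analysis/00_config.R")

data_dir <- file.path(RESULTS, "data")
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

for (i in c(seq_len(N_DATASETS), 17L)) {
  id <- if (i == 17L) "calibration" else DATASET_IDS[i]
  d <- generate_dataset(dataset_params(i))
  write_expression(d$expression, file.path(data_dir, paste0(id, "_expression.tsv")))
  write_sample_design(d$design, file.path(data_dir, paste0(id, "_design.tsv")))
  utils::write.table(
    data.frame(probe_id = names(d$annotation), gene_symbol = d$annotation),
    file.path(data_dir, paste0(id, "_annotation.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_sets(generate_gene_sets(d$truth),
                  file.path(data_dir, paste0(id, "_gene_sets.gmt")))
  jsonlite::write_json(
    d$truth[c("gene_module", "bridge_mixing", "peripheral_module")],
    file.path(data_dir, paste0(id, "_truth.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cat(sprintf("%s: %d probes x %d samples, %d planted bridges\n", id,
              nrow(d$expression), ncol(d$expression),
              sum(d$truth$gene_module == "bridge")))
}
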