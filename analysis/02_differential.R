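# Differential regulation: per-probe two-way ANOVA (condition + time) on
# the treated samples, BH adjustment, and fold change against the
# untreated baseline controls; probes pass at adjusted p < 0.05 and
# fold change >= 2. Writes one table per dataset.

source("analysis/00_config.R")
data_dir <- file.path(RESULTS, "data")

for (id in c(DATASET_IDS, "calibration")) {
  mat <- read_expression(file.path(data_dir, paste0(id, "_expression.tsv")))
  design <- read_sample_design(file.path(data_dir, paste0(id, "_design.tsv")))
  de <- select_differential(mat, design, alpha = 0.05, fc_threshold = 2.0)
  utils::write.table(de, file.path(RESULTS, paste0(id, "_diffexpr.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d of %d probes differentially regulated\n",
              id, sum(de$selected), nrow(de)))
}
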