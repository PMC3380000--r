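# Shared configuration for the analysis scripts. Run the scripts in order
# from the repository root:
#
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_differential.R
#   ...
#
# Everything downstream is reproducible from this one seed.

suppressPackageStartupMessages(library(bottlenet))

STUDY_SEED <- 1234L
N_DATASETS <- 3L
RESULTS <- "results/analysis"
DATASET_IDS <- sprintf("net%d", seq_len(N_DATASETS))

dataset_params <- function(i) {
  p <- synthetic_params()
  p$seed <- STUDY_SEED + as.integer(i)   # i = 17 is the calibration dataset
  p
}

dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)
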