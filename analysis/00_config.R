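# Shared settings for the analysis scripts. Run the scripts in order from
# the repository root:
#   Rscript analysis/01_cohort.R
#   Rscript analysis/02_simulate_arrays.R
#   ...
# Every script is a thin driver over the cfsmedip package; all outputs land
# under results/.

suppressPackageStartupMessages(library(cfsmedip))

SEED <- 20130428L
DATA_DIR <- "results/data"
OUT_DIR <- "results"
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

STUDY_CONFIG <- simulation_config(n_genes = 1000, seed = SEED)
STUDY_MIXTURE <- mixture_model(seed = SEED)
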