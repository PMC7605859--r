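# Shared settings for the analysis scripts: one seed drives every stage,
# and all tables land under results/. Resting-state series are
# regenerated deterministically from the seed in each script that needs
# them rather than stored (287 x 240 x 36 values).
library(langlat)

ANALYSIS_SEED <- 20201016L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

analysis_config <- function() default_cohort_config(seed = ANALYSIS_SEED)
analysis_atlas <- function() default_atlas()
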