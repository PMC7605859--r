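# Stage 2 — derive the nine clustering features.
#
# Task side: volumetric-mean left-minus-right asymmetries for each task
# (PROD, LISN, READ) over SENT_CORE (18 pairs) and SENT_HUBS (F3t, STS3,
# STS4). Rest side: series are cleaned (trend regression + 0.01-0.1 Hz
# zero-phase FIR), correlated, and summarized as per-hemisphere degree
# centrality (sum of positive ipsilateral correlations, averaged over
# the 18 hROIs) and the Fisher-averaged homotopic correlation.
source("analysis/00_config.R")

cfg <- analysis_config()
atlas <- analysis_atlas()

contrasts <- read.delim(file.path(RESULTS_DIR, "contrasts.tsv"))
cohort <- read.delim(file.path(RESULTS_DIR, "participants.tsv"))

profiles <- asymmetry_profiles(contrasts, atlas)
rest <- suppressWarnings(generate_rest_timeseries(cohort, atlas, cfg))
metrics <- connectivity_metrics(rest, atlas)

write.table(profiles, file.path(RESULTS_DIR, "asymmetries.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(metrics, file.path(RESULTS_DIR, "metrics.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

g <- cohort$latent_group[match(profiles$id, cohort$id)]
cat("Group means of the features (latent truth):\n")
print(aggregate(cbind(CORE_PROD = profiles$CORE_PROD,
                      rs_dc_mean = metrics$rs_dc_mean,
                      mihhc = metrics$mihhc_r), list(group = g), mean),
      digits = 3)
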