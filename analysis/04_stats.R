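# Stage 4 — group-level statistics on the recovered classification.
#
# Repeated-measures MANOVA of absolute task asymmetries (task x language
# organization x handedness, Pillai), Tukey HSD on the resting-state
# degree centrality, chi-square proportion tests for handedness and sex,
# covariate-residualized anatomy comparisons, and promax-rotated PCA of
# the residualized cognitive battery.
source("analysis/00_config.R")

cohort <- read.delim(file.path(RESULTS_DIR, "participants.tsv"))
profiles <- read.delim(file.path(RESULTS_DIR, "asymmetries.tsv"))
metrics <- read.delim(file.path(RESULTS_DIR, "metrics.tsv"))
labels <- read.delim(file.path(RESULTS_DIR, "labels.tsv"))
cognition <- read.delim(file.path(RESULTS_DIR, "cognition.tsv"))
anatomy <- read.delim(file.path(RESULTS_DIR, "anatomy.tsv"))

g <- factor(labels$group, levels = c("TYP_STRONG", "TYP_MILD", "ATYP"))
hand <- factor(cohort$handedness[match(labels$id, cohort$id)])

effects <- list()
for (rs in c("CORE", "HUBS")) {
  dep <- profiles[, paste0("ABS_", rs, "_", c("PROD", "LISN", "READ"))]
  effects[[rs]] <- repeated_manova(
    dep, data.frame(organization = g, handedness = hand),
    data.frame(task = c("PROD", "LISN", "READ")))
  cat("\nAbsolute", rs, "asymmetries (Pillai):\n")
  print(effects[[rs]], digits = 3)
}

cat("\nTukey HSD on mean degree centrality:\n")
tk <- tukey_hsd(metrics$rs_dc_mean[match(labels$id, metrics$id)], g)
print(tk, digits = 3)

cat("\nHandedness by organization (chi-square):\n")
print(unlist(proportion_test(table(g, hand))))

covs <- data.frame(id = cohort$id, age = cohort$age, sex = cohort$sex,
                   handedness = cohort$handedness, tiv = cohort$tiv_cc)
anat <- anatomy_comparison(anatomy, labels, covs)
cat("\nAnatomy (asymmetries, repeated over compartment):\n")
print(anat$asym_effects, digits = 3)
cat("\nCorpus callosum ANOVA:\n")
print(anat$cc_effects, digits = 3)

cog_res <- residualize(cognition[, -1L],
                       covs[match(cognition$id, covs$id),
                            c("age", "sex", "handedness", "tiv")])
pca <- pca_promax(cog_res)
cat("\nPCA of cognitive residuals: retained", pca$n_components,
    "components (", pca$retention_rule, "rule ),",
    round(sum(pca$variance_explained), 1), "% variance\n")
print(round(pca$loadings, 2))

jsonlite::write_json(
  list(manova = effects, tukey_dc = tk,
       anatomy_asym = anat$asym_effects, cc = anat$cc_effects,
       pca_n_components = pca$n_components,
       pca_variance_pct = sum(pca$variance_explained)),
  file.path(RESULTS_DIR, "effects.json"), auto_unbox = TRUE, digits = 6,
  dataframe = "rows")
write.table(cbind(test = rownames(pca$loadings), round(pca$loadings, 4)),
            file.path(RESULTS_DIR, "pca_loadings.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
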