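#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> features -> classify -> stats -> compare:
#' generates (or accepts) the cohort tables, computes the task-asymmetry
#' profiles and resting-state connectivity metrics, clusters participants
#' (Ward + validity-index vote), labels phenotypes and dissociations,
#' runs the group statistics and the concordance comparison against
#' synthetic external labels, writes every tabular artifact to
#' `out_dir` (tab-delimited, with headers) and returns a machine-readable
#' run report.
#'
#' @param config A `cohort_config` (see [default_cohort_config()]);
#'   `config$seed` drives every stage.
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @param atlas Atlas data frame; default [default_atlas()].
#' @param threshold Dissociation band half-width.
#' @param k_range Candidate cluster numbers for the validity vote.
#' @param write_rest Also write the per-participant resting-state series
#'   (one `rest/<id>.tsv` each; large).
#' @return Invisible list with all stage objects plus `report`.
#' @export
run_pipeline <- function(config = default_cohort_config(),
                         out_dir = NULL, atlas = default_atlas(),
                         threshold = 0.05, k_range = 2:8,
                         write_rest = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  cohort <- generate_cohort(config)
  contrasts <- generate_task_contrasts(cohort, atlas, config)
  rest <- generate_rest_timeseries(cohort, atlas, config)
  cognition <- generate_cognitive_scores(cohort, config)
  anatomy <- generate_anatomy(cohort, config)

  profiles <- asymmetry_profiles(contrasts, atlas)
  metrics <- connectivity_metrics(rest, atlas)

  fz <- build_features(profiles, metrics, standardize = TRUE)
  fr <- build_features(profiles, metrics, standardize = FALSE)
  tree <- ward_tree(fz)
  sel <- select_k(fz, tree, k_range = k_range)
  groups <- assign_groups(fr, tree, k = 3L)
  diss <- classify_dissociation(profiles, threshold = threshold)
  labels <- merge(groups, diss, by = "id", sort = FALSE)

  # group statistics on the recovered labels
  g <- factor(labels$group,
              levels = intersect(c("TYP_STRONG", "TYP_MILD", "ATYP"),
                                 unique(labels$group)))
  abs_cols <- paste0("ABS_", c("CORE_PROD", "CORE_LISN", "CORE_READ"))
  hand <- cohort$handedness[match(labels$id, cohort$id)]
  manova_core <- repeated_manova(
    profiles[, abs_cols],
    data.frame(organization = g, handedness = factor(hand)),
    data.frame(task = factor(c("PROD", "LISN", "READ"))))
  tukey_dc <- tukey_hsd(metrics$rs_dc_mean[match(labels$id, metrics$id)], g)
  prop_hand <- proportion_test(table(g, hand))
  covs <- data.frame(id = cohort$id, age = cohort$age,
                     sex = cohort$sex, handedness = cohort$handedness,
                     tiv = cohort$tiv_cc)
  anat <- anatomy_comparison(anatomy, labels, covs)
  cog_res <- residualize(cognition[, -1L],
                         covs[match(cognition$id, covs$id),
                              c("age", "sex", "handedness", "tiv")])
  pca <- pca_promax(cog_res)
  ext <- synthetic_external_labels(labels, seed = config$seed)
  conc <- cross_tabulate(stats::setNames(labels$group, labels$id),
                         stats::setNames(ext$gmm_label, ext$id))
  flows <- alluvial_table(merge(labels, ext, by = "id"),
                          c("gmm_label", "group", "svm_right"))

  report <- list(
    package_version = as.character(utils::packageVersion("langlat")),
    seed = config$seed,
    n_participants = nrow(cohort),
    n_left_handers = sum(cohort$handedness == "L"),
    n_women = sum(cohort$sex == "F"),
    selected_k = sel$k,
    votes = as.list(sel$votes),
    group_sizes = as.list(table(labels$group)),
    dissociation_counts = as.list(table(labels$dissociation)),
    ari_vs_latent = mclust::adjustedRandIndex(
      labels$group, cohort$latent_group[match(labels$id, cohort$id)]),
    manova_task_by_organization_p =
      manova_core$p_value[manova_core$effect == "organization:task"],
    pca_n_components = pca$n_components,
    gmm_concordance_ari = conc$ari,
    elapsed_s = proc.time()[["elapsed"]] - t0)

  out <- list(config = config, cohort = cohort, contrasts = contrasts,
              cognition = cognition, anatomy = anatomy,
              profiles = profiles, metrics = metrics,
              features = fr, tree = tree, selection = sel,
              labels = labels, manova_core = manova_core,
              tukey_dc = tukey_dc, prop_hand = prop_hand,
              anatomy_stats = anat, pca = pca,
              external = ext, concordance = conc, flows = flows,
              report = report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(cohort, "participants.tsv")
    wt(contrasts, "contrasts.tsv")
    wt(cognition, "cognition.tsv")
    wt(anatomy, "anatomy.tsv")
    wt(profiles, "asymmetries.tsv")
    wt(metrics, "metrics.tsv")
    wt(data.frame(id = rownames(fr), fr), "features.tsv")
    wt(labels, "labels.tsv")
    wt(flows, "flows.tsv")
    wt(as.data.frame(conc$table), "contingency.tsv")
    jsonlite::write_json(as.list(sel$votes), file.path(out_dir, "votes.json"),
                         auto_unbox = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (write_rest) {
      dir.create(file.path(out_dir, "rest"), showWarnings = FALSE)
      for (id in names(rest))
        utils::write.table(round(rest[[id]], 5),
                           file.path(out_dir, "rest", paste0(id, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(out)
}
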