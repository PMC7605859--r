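test_that("cohort generation reproduces the configured quotas exactly", {
  coh <- generate_cohort(default_cohort_config(seed = 5))
  expect_equal(nrow(coh), 287L)
  expect_equal(sum(coh$handedness == "L"), 150L)
  expect_equal(sum(coh$sex == "F"), 140L)
  expect_equal(as.vector(table(coh$latent_group)[c("TYP_STRONG",
                                                   "TYP_MILD", "ATYP")]),
               c(125L, 132L, 30L))
  expect_equal(as.vector(table(coh$latent_group,
                               coh$latent_dissociation)[
    c("TYP_STRONG", "TYP_MILD", "ATYP"), "CROSSED"]), c(2L, 9L, 12L))
  # 17 of the 23 crossed are left-handers; 9 of 12 crossed ATYP majority
  expect_equal(sum(coh$handedness == "L" &
                     coh$latent_dissociation == "CROSSED"), 17L)
  expect_equal(sum(coh$latent_crossed_subtype == "PROD_LEFT",
                   na.rm = TRUE), 9L)
})

test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(default_cohort_config(seed = 11))
  b <- generate_cohort(default_cohort_config(seed = 11))
  expect_identical(a, b)
  c <- generate_cohort(default_cohort_config(seed = 12))
  expect_false(identical(a, c))
})

test_that("infeasible quotas raise config errors", {
  cfg <- default_cohort_config()
  cfg$left_handers[["ATYP"]] <- 31L
  expect_error(validate_cohort_config(cfg), "quota")
  cfg <- default_cohort_config()
  cfg$group_sizes[["ATYP"]] <- 31L
  expect_error(validate_cohort_config(cfg), "n_total")
  cfg <- default_cohort_config()
  cfg$crossed_left_handers[["TYP_MILD"]] <- 10L
  expect_error(validate_cohort_config(cfg), "crossed")
})

test_that("rest template calibration inverts the degree-centrality map", {
  # boundary case: maximum DC maps to uniform r = 1 (degenerate template
  # whose PSD repair cannot keep the cross-hemisphere targets)
  tpl_max <- suppressWarnings(calibrate_rest_template(17, 17, 0.3))
  expect_equal(tpl_max$within_left_r, 1.0)
  tpl <- calibrate_rest_template(8.67, 8.67, 0.61)
  expect_equal(tpl$within_left_r, 8.67 / 17)
  expect_equal(tpl$homotopic_r, 0.61)
  # implied metrics of the assembled matrix match the targets
  imp <- langlat:::template_implied_metrics(tpl$sigma)
  expect_equal(imp$dc_left, 8.67, tolerance = 1e-10)
  expect_equal(imp$mihhc, 0.61, tolerance = 1e-10)
  expect_error(calibrate_rest_template(18, 8, 0.5), "DC")
  expect_error(calibrate_rest_template(8, 8, 1.2), "mihhc")
})

test_that("rest series reproduce the template correlations at large n", {
  cfg <- default_cohort_config(seed = 3)
  cfg$n_timepoints <- 50000L
  cfg$rest_params <- lapply(cfg$rest_params, function(p) {
    p[c("dc_mean_sd", "dc_asym_sd")] <- 0; p })
  cfg$rest_jitter_sd <- 0
  coh <- generate_cohort(cfg)[1L, , drop = FALSE]
  atl <- default_atlas()
  series <- generate_rest_timeseries(coh, atl, cfg)[[1L]]
  expect_equal(dim(series), c(50000L, 36L))
  tpl <- calibrate_rest_template(8.920, 8.420, 0.571)
  expect_lt(max(abs(cor(series) - tpl$sigma)), 0.02)
})

test_that("rest series have the configured shape and are seed-stable", {
  cfg <- default_cohort_config(seed = 4)
  coh <- generate_cohort(cfg)[1:3, ]
  atl <- default_atlas()
  a <- suppressWarnings(generate_rest_timeseries(coh, atl, cfg))
  b <- suppressWarnings(generate_rest_timeseries(coh, atl, cfg))
  expect_identical(a, b)
  expect_equal(dim(a[[1L]]), c(240L, 36L))
  expect_equal(attr(a[[1L]], "tr"), 2)
})

test_that("task contrasts reproduce drawn network targets and calibration", {
  run <- cohort_classification_run(1)
  coh <- run$cohort; prof <- run$profiles
  g <- coh$latent_group[match(prof$id, coh$id)]
  # TYP_STRONG mean SENT_CORE PROD asymmetry within 2 se of 0.557
  expect_lt(abs(mean(prof$CORE_PROD[g == "TYP_STRONG"]) - 0.557),
            2 * 0.17 / sqrt(125))
  # crossed ATYP majority: PROD leftward, LISN/READ rightward
  cr <- coh$id[coh$latent_dissociation == "CROSSED" &
                 coh$latent_group == "ATYP" &
                 coh$latent_crossed_subtype == "PROD_LEFT"]
  sub <- prof[prof$id %in% cr, ]
  expect_true(all(sub$CORE_PROD > 0.05))
  expect_true(all(sub$CORE_LISN < -0.05 & sub$CORE_READ < -0.05))
})

test_that("zero asymmetry targets with zero noise give symmetric contrasts", {
  cfg <- default_cohort_config(seed = 6)
  cfg$task_roi_noise_sd <- 0
  for (rs in names(cfg$task_asym_params))
    for (task in names(cfg$task_asym_params[[rs]]))
      cfg$task_asym_params[[rs]][[task]][, ] <- 0
  coh <- generate_cohort(cfg)
  coh <- coh[coh$latent_dissociation == "CONGRUENT", ][1:5, ]
  atl <- default_atlas()
  ct <- generate_task_contrasts(coh, atl, cfg)
  l <- ct$bold[ct$hemisphere == "L"]
  r <- ct$bold[ct$hemisphere == "R"]
  expect_equal(l, r, tolerance = 1e-12)
})

test_that("cognitive scores follow the latent factor model", {
  cfg <- default_cohort_config(seed = 7)
  coh <- generate_cohort(cfg)
  cg <- generate_cognitive_scores(coh, cfg)
  expect_equal(names(cg)[-1L], cfg$cognitive$tests)
  expect_equal(nrow(cg), 287L)
  # zero noise and covariate effects: correlation matrix of rank <= 4
  cg0 <- generate_cognitive_scores(coh, cfg, noise_sd = 0,
                                   covariate_scale = 0)
  ev <- eigen(cor(as.matrix(cg0[, -1L])), only.values = TRUE)$values
  expect_lt(ev[5L], 1e-3)  # only rounding of the reported scores remains
  expect_gt(ev[4L], 0.01)
  # wrong loading shape errors
  cfg$cognitive$loadings <- cfg$cognitive$loadings[, 1:3]
  expect_error(generate_cognitive_scores(coh, cfg), "11 x 4")
})

test_that("anatomy reconstruction matches drawn asymmetries and cells", {
  cfg <- default_cohort_config(seed = 8)
  coh <- generate_cohort(cfg)
  an <- generate_anatomy(coh, cfg)
  expect_identical(an, generate_anatomy(coh, cfg))
  # zero-sd cells reproduce the configured means exactly
  cfg0 <- cfg
  for (nm in names(cfg0$anatomy)) cfg0$anatomy[[nm]][, "sd"] <- 0
  an0 <- generate_anatomy(coh, cfg0)
  typ_cong <- coh$latent_group != "ATYP" &
    coh$latent_dissociation == "CONGRUENT"
  expect_equal(unique(round(an0$gm_left[typ_cong] -
                              an0$gm_right[typ_cong], 10)), 11.35)
  expect_equal(unique(round(an0$cc_volume[typ_cong], 10)), 5.31)
  # large-sample TYP congruent mean near the configured cell mean
  expect_lt(abs(mean(an$gm_left[typ_cong] - an$gm_right[typ_cong]) - 11.35),
            2 * 4.0 / sqrt(sum(typ_cong)))
})
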