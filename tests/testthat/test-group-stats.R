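test_that("residualize removes covariates and is idempotent", {
  # frozen oracle: lm() on y = (1,2,3,5), x = (0,1,2,3) gives slope 1.3,
  # intercept 0.8, residuals (0.2, -0.1, -0.4, 0.3)
  y <- data.frame(score = c(1, 2, 3, 5))
  x <- data.frame(x = c(0, 1, 2, 3))
  r <- residualize(y, x)
  expect_equal(r$score, c(0.2, -0.1, -0.4, 0.3))
  expect_equal(unname(coef(lm(score ~ x, cbind(y, x)))), c(0.8, 1.3))
  # empty covariate set mean-centers
  r0 <- residualize(y)
  expect_equal(r0$score, y$score - mean(y$score))
  # residuals are orthogonal to every numeric covariate; idempotent
  set.seed(4)
  yy <- data.frame(a = rnorm(50), b = rnorm(50))
  cv <- data.frame(age = rnorm(50), sex = sample(c("F", "M"), 50, TRUE))
  rr <- residualize(yy, cv)
  expect_lt(abs(cor(rr$a, cv$age)), 1e-10)
  expect_equal(residualize(rr, cv), rr, tolerance = 1e-10)
  cv_bad <- cbind(cv, age2 = cv$age)
  expect_error(residualize(yy, cv_bad), "collinear")
})

test_that("repeated-measures MANOVA reports the requested Pillai tests", {
  set.seed(6)
  dep <- matrix(rnorm(90 * 3), 90, 3)
  between <- data.frame(g = rep(c("a", "b", "c"), each = 30),
                        h = rep(c("L", "R"), 45))
  within <- data.frame(task = c("PROD", "LISN", "READ"))
  et <- repeated_manova(dep, between, within)
  expect_setequal(et$effect, c("g", "h", "g:h", "task", "g:task",
                               "h:task", "g:h:task"))
  expect_true(all(is.finite(et$value) & is.finite(et$p_value)))
  expect_true(all(et$p_value >= 0 & et$p_value <= 1))
  expect_error(repeated_manova(cbind(dep, NA), between,
                               rbind(within, "X")), "missing")
})

test_that("the task-by-organization interaction is detected on the cohort", {
  run <- cohort_classification_run(1)
  prof <- run$profiles
  g <- run$cohort$latent_group[match(prof$id, run$cohort$id)]
  et <- repeated_manova(
    prof[, c("ABS_CORE_PROD", "ABS_CORE_LISN", "ABS_CORE_READ")],
    data.frame(organization = g),
    data.frame(task = c("PROD", "LISN", "READ")))
  expect_lt(et$p_value[et$effect == "organization:task"], 1e-4)
  expect_lt(et$p_value[et$effect == "task"], 1e-4)
})

test_that("Tukey HSD separates shifted groups and not identical ones", {
  set.seed(8)
  vals <- c(rnorm(30), rnorm(30), rnorm(30, 5))
  grp <- rep(c("g1", "g2", "g3"), each = 30)
  tk <- tukey_hsd(vals, grp)
  expect_equal(nrow(tk), 3L)
  expect_gt(tk$p_adj[tk$group_a == "g2" & tk$group_b == "g1"], 0.5)
  expect_lt(max(tk$p_adj[tk$group_b == "g3" | tk$group_a == "g3"]), 1e-4)
  # two identical groups: adjusted p near 1
  v2 <- rep(c(1, 2, 3), 2)
  tk2 <- tukey_hsd(v2, rep(c("a", "b"), each = 3))
  expect_gt(tk2$p_adj, 0.99)
  expect_error(tukey_hsd(1:3, c("a", "a", "b")), "fewer than 2")
})

test_that("proportion test is Pearson chi-square without correction", {
  res <- proportion_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # crossed-by-handedness counts: significant at 0.05
  res2 <- proportion_test(matrix(c(17, 133, 6, 131), 2))
  expect_lt(res2$p_value, 0.05)
  expect_equal(res2$statistic,
               unname(suppressWarnings(chisq.test(
                 matrix(c(17, 133, 6, 131), 2),
                 correct = FALSE)$statistic)))
  expect_equal(proportion_test(matrix(1:6, 2))$df, 2)
  expect_error(proportion_test(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(proportion_test(matrix(c(-1, 2, 1, 2), 2)), "non-negative")
})

test_that("PCA recovers a planted four-factor structure", {
  hits <- 0L; congr85 <- 0L; congr90 <- 0L
  cfgL <- default_cohort_config()$cognitive$loadings
  for (s in 1:10) {
    cfg <- default_cohort_config(seed = s)
    coh <- generate_cohort(cfg)
    cg <- generate_cognitive_scores(coh, cfg)
    covs <- data.frame(age = coh$age, sex = coh$sex,
                       handedness = coh$handedness, tiv = coh$tiv_cc)
    p <- pca_promax(residualize(cg[, -1L], covs))
    if (p$n_components == 4L) {
      hits <- hits + 1L
      # Tucker congruence between generating and rotated loadings after
      # greedy column matching
      congr <- apply(cfgL, 2L, function(gen)
        max(abs(colSums(gen * p$loadings) /
                  sqrt(sum(gen^2) * colSums(p$loadings^2)))))
      if (min(congr) >= 0.85) congr85 <- congr85 + 1L
      if (min(congr) > 0.9) congr90 <- congr90 + 1L
    }
  }
  expect_gte(hits, 8L)
  # the three strong factors recover cleanly; the verbal factor is weak
  # by construction (loadings 0.31-0.64), so its congruence tail is wider
  expect_gte(congr85, 8L)
  expect_gte(congr90, 5L)
})

test_that("PCA handles exact low-rank and fixed retention", {
  set.seed(8)
  f <- matrix(rnorm(300 * 2), 300, 2)
  L <- cbind(c(0.9, 0.8, 0.7, 0.6, 0, 0, 0, 0),
             c(0, 0, 0, 0, 0.9, 0.8, 0.7, 0.6))
  x <- f %*% t(L)
  p <- pca_promax(x)
  expect_equal(p$n_components, 2L)
  expect_lt(p$eigenvalues[3L], 1e-8)
  p4 <- suppressWarnings(pca_promax(x, retain = 4))
  expect_equal(ncol(p4$loadings), 4L)
  expect_error(pca_promax(x, retain = 12), "retain")
  expect_error(pca_promax(x[1:5, ]), "observations")
  expect_lt(sum(pca_promax(x, retain = 2)$variance_explained) - 100, 1e-8)
})

test_that("anatomy comparison returns the requested effects", {
  run <- cohort_classification_run(1)
  cfg <- run$config
  an <- generate_anatomy(run$cohort, cfg)
  labels <- data.frame(id = run$cohort$id,
                       group = run$cohort$latent_group,
                       dissociation = run$cohort$latent_dissociation)
  covs <- data.frame(id = run$cohort$id, age = run$cohort$age,
                     sex = run$cohort$sex,
                     handedness = run$cohort$handedness,
                     tiv = run$cohort$tiv_cc)
  res <- anatomy_comparison(an, labels, covs)
  expect_true("organization" %in% res$asym_effects$effect)
  expect_true("organization:compartment" %in% res$asym_effects$effect)
  expect_true("org:diss" %in% res$cc_effects$effect)
  expect_equal(nrow(res$cc_posthoc), 6L)  # 4 cells -> 6 pairs
  # covariate-free call equals direct ANOVA on centered values
  res0 <- anatomy_comparison(an, labels, covariates = NULL)
  org <- factor(ifelse(labels$group == "ATYP", "ATYP", "TYP"))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- lm(an$cc_volume ~ org * factor(labels$dissociation))
  av <- car::Anova(fit, type = "III")
  expect_equal(res0$cc_effects$p_value[res0$cc_effects$effect == "org"],
               av[["Pr(>F)"]][rownames(av) == "org"], tolerance = 1e-8)
})
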