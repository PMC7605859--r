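#' Generate cognitive test scores with a four-factor latent structure
#'
#' Scores on the 11-test battery (7 verbal, 4 visuospatial) follow a
#' linear factor model: per participant, four latent factors (SPA, PHONO,
#' MEM, VERB) are drawn standard normal around group-specific shifts, test
#' scores combine the configured 11 x 4 loading matrix, linear covariate
#' effects (age, education, sex, handedness, intracranial volume, in sd
#' units) and unique noise scaled so each standardized test has unit
#' variance at zero covariate effect, and are then mapped to each test's
#' marginal scale (pooled mean/sd of the printed group cells).
#'
#' @param cohort Participant table from [generate_cohort()].
#' @param config A `cohort_config`; `config$cognitive` holds loadings,
#'   group factor shifts, covariate effects and test scales.
#' @param noise_sd Multiplier on the unique-noise standard deviation
#'   (0 gives an exact rank-<=-4 factor model when covariate effects are
#'   also zero).
#' @param covariate_scale Multiplier on the covariate effects.
#' @return `data.frame` with `id` plus one column per test.
#' @export
generate_cognitive_scores <- function(cohort,
                                      config = default_cohort_config(),
                                      noise_sd = 1, covariate_scale = 1) {
  cg <- config$cognitive
  L <- cg$loadings
  if (!is.matrix(L) || nrow(L) != length(cg$tests) || ncol(L) != 4L)
    stop("loading matrix must be ", length(cg$tests), " x 4")
  set.seed(stage_seed(config, "cognition"))
  n <- nrow(cohort)
  shifts <- cg$shifts[cohort$latent_group, , drop = FALSE]
  f <- shifts + matrix(stats::rnorm(n * 4L), n, 4L)
  common <- f %*% t(L)
  uniq_sd <- sqrt(pmax(1 - rowSums(L^2), 0.05))  # unit total variance
  e <- matrix(stats::rnorm(n * nrow(L)), n, nrow(L)) %*%
    diag(uniq_sd * noise_sd)
  covs <- cbind(age = scale(cohort$age)[, 1L],
                education = scale(cohort$education)[, 1L],
                sexF = as.numeric(cohort$sex == "F"),
                handL = as.numeric(cohort$handedness == "L"),
                tiv = scale(cohort$tiv_cc)[, 1L])
  ce <- covs %*% (cg$covariate_effects * covariate_scale)
  z <- sweep(common + e, 1L, -ce[, 1L])  # add covariate effect to every test
  scores <- sweep(sweep(z, 2L, cg$scale$sd, `*`), 2L, cg$scale$mean, `+`)
  out <- data.frame(id = cohort$id, round(scores, 2),
                    stringsAsFactors = FALSE)
  names(out) <- c("id", cg$tests)
  out
}

#' Generate hemispheric anatomy and corpus callosum volumes
#'
#' Gray-matter, white-matter and corpus-callosum volumes (cc) are drawn per
#' organization (TYP = TYP_STRONG + TYP_MILD pooled, vs ATYP) by
#' dissociation cell from the configured means/sds. For each compartment a
#' base (mean of the hemispheres) and an asymmetry are drawn, and
#' hemispheric volumes are reconstructed as left = base + asym/2,
#' right = base - asym/2, so left minus right reproduces the drawn
#' asymmetry exactly.
#'
#' @param cohort Participant table from [generate_cohort()].
#' @param config A `cohort_config`; cells in `config$anatomy`.
#' @return `data.frame` with `id`, `gm_left`, `gm_right`, `wm_left`,
#'   `wm_right`, `cc_volume` (all cc).
#' @export
generate_anatomy <- function(cohort, config = default_cohort_config()) {
  set.seed(stage_seed(config, "anatomy"))
  an <- config$anatomy
  org <- ifelse(cohort$latent_group == "ATYP", "ATYP", "TYP")
  cell <- paste(org, cohort$latent_dissociation, sep = ".")
  n <- nrow(cohort)
  draw <- function(tab) stats::rnorm(n, tab[cell, "mean"], tab[cell, "sd"])
  gm_base <- draw(an$gm_base); gm_asym <- draw(an$gm_asym)
  wm_base <- draw(an$wm_base); wm_asym <- draw(an$wm_asym)
  data.frame(id = cohort$id,
             gm_left = gm_base + gm_asym / 2,
             gm_right = gm_base - gm_asym / 2,
             wm_left = wm_base + wm_asym / 2,
             wm_right = wm_base - wm_asym / 2,
             cc_volume = draw(an$cc_vol),
             stringsAsFactors = FALSE)
}
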