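#' Default configuration of the synthetic cohort
#'
#' Returns the configuration of the synthetic study cohort: 287
#' participants (150 left-handers, 140 women) split into three latent
#' lateralization phenotypes -- TYP_STRONG (n = 125), TYP_MILD (n = 132)
#' and ATYP (n = 30) -- with exact per-group quotas for handedness, sex
#' and crossed (dissociated) lateralization, task-asymmetry distributions
#' per group x task x ROI set, resting-state connectivity targets per
#' group, a four-factor cognitive battery and hemispheric anatomy cells.
#' Group quotas are deterministic counts, not Bernoulli draws, so the
#' marginal counts are reproduced exactly at every seed.
#'
#' Defaults calibrate every cell to the study's descriptive tables; see
#' the package vignette for the provenance of each number and for the
#' choices made where the tables are silent.
#'
#' @param n_total Total cohort size.
#' @param seed Integer seed from which all generator streams are derived.
#' @return A list of class `cohort_config`.
#' @export
default_cohort_config <- function(n_total = 287L, seed = 1L) {
  groups <- c("TYP_STRONG", "TYP_MILD", "ATYP")
  cfg <- list(
    n_total = as.integer(n_total),
    seed = as.integer(seed),
    groups = groups,
    group_sizes = c(TYP_STRONG = 125L, TYP_MILD = 132L, ATYP = 30L),
    left_handers = c(TYP_STRONG = 58L, TYP_MILD = 67L, ATYP = 25L),
    women = c(TYP_STRONG = 48L, TYP_MILD = 77L, ATYP = 15L),
    crossed = c(TYP_STRONG = 2L, TYP_MILD = 9L, ATYP = 12L),
    # of the crossed members, how many are left-handed (total 17 of 23)
    crossed_left_handers = c(TYP_STRONG = 1L, TYP_MILD = 6L, ATYP = 10L),
    # of the 12 crossed ATYP, 9 show PROD-left / perception-right; 3 reversed
    atyp_crossed_majority = 9L,
    age_mean = 25.8, age_sd = 6.5,
    education_mean = 15.6, education_sd = 2.3,
    edinburgh_left = c(mean = -63.2, sd = 39.9),
    edinburgh_right = c(mean = 92, sd = 12),
    tiv_mean = 1450, tiv_sd = 120,
    # task-asymmetry calibration: mean (sd) per group for each task and
    # ROI set, on the left-minus-right BOLD difference scale
    task_asym_params = list(
      SENT_CORE = list(
        PROD = rbind(TYP_STRONG = c(0.557, 0.17), TYP_MILD = c(0.296, 0.12),
                     ATYP = c(-0.114, 0.19)),
        LISN = rbind(TYP_STRONG = c(0.299, 0.13), TYP_MILD = c(0.167, 0.09),
                     ATYP = c(-0.155, 0.17)),
        READ = rbind(TYP_STRONG = c(0.351, 0.18), TYP_MILD = c(0.217, 0.14),
                     ATYP = c(-0.177, 0.15))),
      SENT_HUBS = list(
        PROD = rbind(TYP_STRONG = c(0.80, 0.23), TYP_MILD = c(0.391, 0.18),
                     ATYP = c(-0.119, 0.30)),
        LISN = rbind(TYP_STRONG = c(0.42, 0.19), TYP_MILD = c(0.210, 0.15),
                     ATYP = c(-0.291, 0.28)),
        READ = rbind(TYP_STRONG = c(0.51, 0.29), TYP_MILD = c(0.287, 0.23),
                     ATYP = c(-0.358, 0.30)))),
    task_base_mean = 1.0, task_base_sd = 0.3,  # shared L/R activation level
    task_roi_noise_sd = 0.10,   # per-hROI zero-weighted-sum noise
    congruent_clamp = 0.04,     # keep congruent draws out of the crossed region
    crossed_floor = 0.06,       # planted crossed tasks exceed the 0.05 band
    # resting-state calibration: per-hemisphere mean degree-centrality
    # targets and homotopic correlation per group (left = mean + asym/2)
    rest_params = list(
      TYP_STRONG = c(dc_left = 8.920, dc_right = 8.420, mihhc = 0.571,
                     dc_mean_sd = 1.42, dc_asym_sd = 0.77),
      TYP_MILD   = c(dc_left = 8.188, dc_right = 7.710, mihhc = 0.578,
                     dc_mean_sd = 1.24, dc_asym_sd = 0.64),
      ATYP       = c(dc_left = 9.3765, dc_right = 9.5435, mihhc = 0.610,
                     dc_mean_sd = 1.60, dc_asym_sd = 0.78)),
    heterotopic_scale = 0.6,    # heterotopic r as fraction of homotopic r
    rest_jitter_sd = 0.05,      # participant-level jitter on homotopic r
    n_timepoints = 240L,
    tr = 2,
    # cognitive battery: 11 tests x 4 latent factors (SPA, PHONO, MEM, VERB)
    cognitive = cognitive_defaults(),
    # anatomy cells (cc): organization x dissociation, Left/Right/Asym per
    # compartment plus corpus callosum volume
    anatomy = anatomy_defaults()
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

cognitive_defaults <- function() {
  tests <- c("word_learning", "pseudoword_learning", "verbal_fluency",
             "reading_span", "listening_span", "vocabulary", "rhyming",
             "mental_rotation", "corsi_block", "maze", "raven")
  L <- matrix(0, 11, 4, dimnames = list(tests,
                                        c("SPA", "PHONO", "MEM", "VERB")))
  L["mental_rotation", "SPA"] <- 0.62
  L["corsi_block", "SPA"] <- 0.39
  L["maze", "SPA"] <- 0.60
  L["raven", "SPA"] <- 0.68
  L["pseudoword_learning", "PHONO"] <- 0.48
  L["rhyming", "PHONO"] <- 0.72
  L["vocabulary", "PHONO"] <- 0.36
  L["word_learning", "MEM"] <- 0.77
  L["pseudoword_learning", "MEM"] <- 0.49
  L["verbal_fluency", "VERB"] <- 0.64
  L["reading_span", "VERB"] <- 0.34
  L["listening_span", "VERB"] <- 0.31
  L["vocabulary", "VERB"] <- 0.31
  # group shifts on latent factors: the estimated component scores of the
  # study (SPA and MEM differ across groups; PHONO and VERB do not)
  shifts <- rbind(TYP_STRONG = c(SPA = 0.29, PHONO = 0, MEM = 0.05, VERB = 0),
                  TYP_MILD   = c(SPA = -0.19, PHONO = 0, MEM = 0.19, VERB = 0),
                  ATYP       = c(SPA = -0.41, PHONO = 0, MEM = -0.57, VERB = 0))
  # marginal scale of each test: pooled mean/sd of the printed group cells
  scale <- data.frame(
    test = tests,
    mean = c(65.46, 35.44, 47.38, 4.02, 4.70, 28.08, 67.57,
             10.81, 5.84, 6.17, 110.27),
    sd = c(7.54, 10.78, 9.82, 1.10, 1.11, 3.83, 5.51,
           4.45, 1.04, 2.50, 10.15))
  covariate_effects <- c(age = -0.10, education = 0.15, sexF = 0.05,
                         handL = 0.00, tiv = 0.05)  # sd units per covariate sd
  list(tests = tests, loadings = L, shifts = shifts, scale = scale,
       covariate_effects = covariate_effects)
}

anatomy_defaults <- function() {
  # rows: TYP_CONGRUENT, TYP_CROSSED, ATYP_CONGRUENT, ATYP_CROSSED
  cells <- c("TYP.CONGRUENT", "TYP.CROSSED", "ATYP.CONGRUENT", "ATYP.CROSSED")
  gm_base  <- rbind(c(321.32, 32), c(331.66, 47), c(332.60, 34), c(311.89, 15))
  gm_asym  <- rbind(c(11.35, 4.00), c(11.87, 4.50), c(9.65, 5.03), c(10.82, 3.82))
  wm_base  <- rbind(c(215.03, 25), c(219.87, 35), c(221.33, 25), c(207.50, 14))
  wm_asym  <- rbind(c(3.33, 2.19), c(4.11, 1.74), c(2.22, 2.41), c(2.23, 2.03))
  cc_vol   <- rbind(c(5.31, 0.85), c(5.21, 0.67), c(5.45, 0.90), c(5.48, 0.74))
  dimnames(gm_base) <- dimnames(gm_asym) <- dimnames(wm_base) <-
    dimnames(wm_asym) <- dimnames(cc_vol) <- list(cells, c("mean", "sd"))
  list(gm_base = gm_base, gm_asym = gm_asym, wm_base = wm_base,
       wm_asym = wm_asym, cc_vol = cc_vol)
}

#' @rdname default_cohort_config
#' @param cfg A `cohort_config` list.
#' @export
validate_cohort_config <- function(cfg) {
  if (sum(cfg$group_sizes) != cfg$n_total)
    stop("group sizes sum to ", sum(cfg$group_sizes),
         ", expected n_total = ", cfg$n_total)
  for (nm in c("left_handers", "women", "crossed"))
    if (any(cfg[[nm]] > cfg$group_sizes))
      stop("infeasible quota: ", nm, " exceeds group size for group ",
           names(which(cfg[[nm]] > cfg$group_sizes))[1L])
  if (any(cfg$crossed_left_handers > cfg$crossed) ||
      any(cfg$crossed_left_handers > cfg$left_handers))
    stop("infeasible quota: crossed_left_handers exceeds crossed or ",
         "left-hander count in some group")
  if (cfg$atyp_crossed_majority > cfg$crossed[["ATYP"]])
    stop("infeasible quota: atyp_crossed_majority > crossed ATYP count")
  stopifnot(cfg$age_sd >= 0, cfg$education_sd >= 0,
            cfg$rest_jitter_sd >= 0, cfg$task_roi_noise_sd >= 0,
            cfg$n_timepoints >= 100L, cfg$tr > 0)
  for (g in cfg$groups) {
    rp <- cfg$rest_params[[g]]
    if (rp[["dc_left"]] < 0 || rp[["dc_left"]] > 17 ||
        rp[["dc_right"]] < 0 || rp[["dc_right"]] > 17)
      stop("rest dc target out of [0, 17] for group ", g)
    if (abs(rp[["mihhc"]]) >= 1) stop("mihhc target out of (-1, 1): ", g)
  }
  invisible(cfg)
}

# deterministic sub-seed per generator stage, all < 2^31
stage_seed <- function(cfg, stage) {
  offs <- c(cohort = 0L, task = 1L, rest = 2L, cognition = 3L,
            anatomy = 4L, pipeline = 5L)
  (abs(cfg$seed) %% 2000000000L) + 1000L * offs[[stage]]
}

#' Generate the participant table of the synthetic cohort
#'
#' One row per participant with demographics and the latent synthetic
#' truth (phenotype group and dissociation status). Handedness, sex,
#' crossed status and the crossed-by-handedness composition are exact
#' quotas assigned to randomly permuted participants within each group,
#' so printed marginal counts are reproduced deterministically while the
#' assignment itself varies with the seed.
#'
#' @param config A `cohort_config`, e.g. [default_cohort_config()].
#' @return A `data.frame` with columns `id`, `latent_group`, `handedness`,
#'   `edinburgh`, `sex`, `age`, `education`, `tiv_cc`,
#'   `latent_dissociation`, `latent_crossed_subtype`.
#' @export
generate_cohort <- function(config = default_cohort_config()) {
  validate_cohort_config(config)
  set.seed(stage_seed(config, "cohort"))
  out <- list()
  for (g in config$groups) {
    n <- config$group_sizes[[g]]
    nl <- config$left_handers[[g]]
    nf <- config$women[[g]]
    nc <- config$crossed[[g]]
    ncl <- config$crossed_left_handers[[g]]
    hand <- rep("R", n)
    hand[sample.int(n, nl)] <- "L"
    # crossed quota split across handedness groups to hit the joint counts
    left_idx <- which(hand == "L"); right_idx <- which(hand == "R")
    crossed <- rep("CONGRUENT", n)
    if (ncl > 0) crossed[sample(left_idx, ncl)] <- "CROSSED"
    if (nc - ncl > 0) crossed[sample(right_idx, nc - ncl)] <- "CROSSED"
    subtype <- rep(NA_character_, n)
    ci <- which(crossed == "CROSSED")
    if (length(ci)) {
      if (g == "ATYP") {
        maj <- sample(ci, config$atyp_crossed_majority)
        subtype[maj] <- "PROD_LEFT"
        subtype[setdiff(ci, maj)] <- "PROD_RIGHT"
      } else if (g == "TYP_MILD") {
        subtype[ci] <- "READ_RIGHT"
      } else {
        subtype[ci] <- "LISN_RIGHT"
      }
    }
    sex <- rep("M", n)
    sex[sample.int(n, nf)] <- "F"
    edb <- ifelse(hand == "L",
                  stats::rnorm(n, config$edinburgh_left[["mean"]],
                               config$edinburgh_left[["sd"]]),
                  stats::rnorm(n, config$edinburgh_right[["mean"]],
                               config$edinburgh_right[["sd"]]))
    edb <- pmin(100, pmax(-100, edb))
    out[[g]] <- data.frame(
      latent_group = g, handedness = hand, edinburgh = round(edb, 1),
      sex = sex,
      age = round(pmax(18, stats::rnorm(n, config$age_mean, config$age_sd)), 1),
      education = round(pmax(8, stats::rnorm(n, config$education_mean,
                                             config$education_sd)), 1),
      tiv_cc = round(stats::rnorm(n, config$tiv_mean, config$tiv_sd), 1),
      latent_dissociation = crossed,
      latent_crossed_subtype = subtype,
      stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, out)
  cohort <- cbind(id = sprintf("S%03d", seq_len(nrow(cohort))), cohort)
  rownames(cohort) <- NULL
  cohort
}
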