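#' Calibrate a block-correlation resting-state template
#'
#' Inverts the degree-centrality definition: with a uniform positive
#' correlation r among the 18 ipsilateral hROIs of one hemisphere, each
#' hROI's degree centrality (sum of positive correlations with the other
#' 17) is 17 r, so a target mean DC maps to r = DC / 17 per hemisphere.
#' Homotopic (left-right same pair) entries are set to the target mean
#' interhemispheric homotopic correlation and heterotopic cross-hemisphere
#' entries to `heterotopic_scale` times it. If the assembled 36 x 36
#' matrix is not positive semi-definite it is repaired to the nearest PSD
#' correlation matrix and the implied metrics re-verified within 0.05.
#'
#' @param target_mean_dc_left,target_mean_dc_right Target mean degree
#'   centrality per hemisphere, in `[0, 17]`.
#' @param target_mihhc Target homotopic correlation, `|r| < 1`.
#' @param heterotopic_scale Heterotopic r as a fraction of homotopic r.
#'   The default 0.6 keeps the participant-level jitter of
#'   [generate_rest_timeseries()] inside the positive-semi-definite
#'   region on both tails (cross-hemisphere correlations close to the
#'   within-hemisphere level leave no feasibility headroom).
#' @param n_pairs Number of homotopic pairs (18).
#' @return A list of class `rest_template` with the correlation matrix
#'   (`sigma`, columns ordered pair-wise L block then R block) and the
#'   calibrated parameters.
#' @export
calibrate_rest_template <- function(target_mean_dc_left,
                                    target_mean_dc_right,
                                    target_mihhc,
                                    heterotopic_scale = 0.6,
                                    n_pairs = 18L) {
  if (target_mean_dc_left < 0 || target_mean_dc_left > n_pairs - 1 ||
      target_mean_dc_right < 0 || target_mean_dc_right > n_pairs - 1)
    stop("target mean DC must lie in [0, ", n_pairs - 1, "]")
  if (abs(target_mihhc) >= 1) stop("|target_mihhc| must be < 1")
  r_left <- target_mean_dc_left / (n_pairs - 1)
  r_right <- target_mean_dc_right / (n_pairs - 1)
  r_hom <- target_mihhc
  r_het <- heterotopic_scale * r_hom
  sigma <- template_sigma(r_left, r_right, r_hom, r_het, n_pairs)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  repaired <- FALSE
  if (min(ev) < -1e-10) {
    sigma <- as.matrix(Matrix::nearPD(sigma, corr = TRUE)$mat)
    repaired <- TRUE
    imp <- template_implied_metrics(sigma, n_pairs)
    if (abs(imp$dc_left - target_mean_dc_left) > 0.05 ||
        abs(imp$dc_right - target_mean_dc_right) > 0.05 ||
        abs(imp$mihhc - target_mihhc) > 0.05)
      warning("PSD repair moved the implied template metrics by more ",
              "than 0.05 from their targets (infeasible combination of ",
              "degree-centrality and homotopic-correlation targets)")
  }
  structure(list(sigma = sigma, within_left_r = r_left,
                 within_right_r = r_right, homotopic_r = r_hom,
                 heterotopic_r = r_het, n_pairs = n_pairs,
                 repaired = repaired),
            class = "rest_template")
}

template_sigma <- function(r_left, r_right, r_hom, r_het, n_pairs) {
  J <- matrix(1, n_pairs, n_pairs)
  A_L <- (1 - r_left) * diag(n_pairs) + r_left * J
  A_R <- (1 - r_right) * diag(n_pairs) + r_right * J
  B <- r_het * J + (r_hom - r_het) * diag(n_pairs)
  rbind(cbind(A_L, B), cbind(t(B), A_R))
}

template_implied_metrics <- function(sigma, n_pairs = 18L) {
  iL <- seq_len(n_pairs); iR <- n_pairs + iL
  dc <- function(idx) {
    s <- sigma[idx, idx]; diag(s) <- 0
    mean(rowSums(pmax(s, 0)))
  }
  list(dc_left = dc(iL), dc_right = dc(iR),
       mihhc = tanh(mean(atanh(sigma[cbind(iL, iR)]))))
}

#' Generate resting-state ROI time series for the cohort
#'
#' Each participant's series is drawn from a zero-mean multivariate
#' Gaussian whose 36 x 36 correlation matrix is the group's calibrated
#' template with participant-level jitter on the correlation parameters:
#' the within-hemisphere correlation levels receive a shared shift
#' (individual overall connectivity level) plus hemisphere-specific
#' shifts, with standard deviations derived from the group's target
#' degree-centrality mean/asymmetry dispersions (`dc_mean_sd`,
#' `dc_asym_sd`: a mean-DC dispersion of `s_m` and an asymmetry
#' dispersion of `s_a` imply a hemisphere-specific r-jitter of
#' `s_a / (17 sqrt(2))` and a shared r-jitter of
#' `sqrt((s_m / 17)^2 - s_a^2 / (2 * 17^2))`); the homotopic correlation
#' receives an independent shift of sd `rest_jitter_sd`. Jittered
#' parameters are clipped to keep the matrix positive semi-definite
#' (progressive shrinkage towards the template with a warning if
#' needed). Series are temporally white with stationary spatial
#' covariance; the connectivity metrics depend only on Pearson
#' correlations, which this preserves.
#'
#' @param cohort Participant table from [generate_cohort()].
#' @param atlas Atlas data frame (defines column order and labels).
#' @param config A `cohort_config`; templates are calibrated from
#'   `config$rest_params` per group.
#' @param templates Optional named list of `rest_template` per group,
#'   overriding the calibration from `config`.
#' @return Named list (participant id) of `n_timepoints x 36` matrices
#'   with column names `<pair>_<hemisphere>` and attribute `tr` (seconds).
#' @export
generate_rest_timeseries <- function(cohort, atlas,
                                     config = default_cohort_config(),
                                     templates = NULL) {
  stopifnot(config$n_timepoints >= 100L)
  set.seed(stage_seed(config, "rest"))
  if (is.null(templates)) {
    templates <- lapply(config$rest_params, function(p)
      calibrate_rest_template(p[["dc_left"]], p[["dc_right"]], p[["mihhc"]],
                              heterotopic_scale = config$heterotopic_scale))
  }
  pairs <- atlas_pairs(atlas)
  np <- length(pairs)
  cn <- c(paste0(pairs, "_L"), paste0(pairs, "_R"))
  tt <- config$n_timepoints
  out <- vector("list", nrow(cohort))
  names(out) <- cohort$id
  for (i in seq_len(nrow(cohort))) {
    g <- cohort$latent_group[i]
    sig <- jitter_template(templates[[g]],
                           dc_jitter_sds(config$rest_params[[g]]),
                           config$rest_jitter_sd, np)
    ch <- chol(sig)
    m <- matrix(stats::rnorm(tt * 2L * np), tt, 2L * np) %*% ch
    colnames(m) <- cn
    attr(m, "tr") <- config$tr
    out[[i]] <- m
  }
  out
}

# shared and hemisphere-specific r-jitter sds implied by the group's
# target mean-DC and DC-asymmetry dispersions
dc_jitter_sds <- function(rest_params, n_partners = 17) {
  s_m <- rest_params[["dc_mean_sd"]] %||% 0
  s_a <- rest_params[["dc_asym_sd"]] %||% 0
  hemi <- s_a / (n_partners * sqrt(2))
  shared2 <- (s_m / n_partners)^2 - s_a^2 / (2 * n_partners^2)
  if (shared2 < 0)
    stop("dc_asym_sd too large relative to dc_mean_sd (no valid ",
         "shared-jitter decomposition)")
  c(shared = sqrt(shared2), hemi = hemi)
}

# jittered, guaranteed-PSD participant covariance from a group template
jitter_template <- function(tpl, dc_sds, homotopic_sd, n_pairs) {
  if (all(dc_sds <= 0) && homotopic_sd <= 0) return(tpl$sigma)
  for (shrink in c(1, 0.5, 0.25, 0.1, 0)) {
    s <- stats::rnorm(1L, 0, dc_sds[["shared"]] * shrink)
    u <- stats::rnorm(2L, 0, dc_sds[["hemi"]] * shrink)
    eh <- stats::rnorm(1L, 0, homotopic_sd * shrink)
    rl <- min(max(tpl$within_left_r + s + u[1L], 0), 0.99)
    rr <- min(max(tpl$within_right_r + s + u[2L], 0), 0.99)
    rh <- min(max(tpl$homotopic_r + eh, -0.99), 0.99)
    sig <- template_sigma(rl, rr, rh, tpl$heterotopic_r, n_pairs)
    ev_min <- min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min > 1e-8) {
      if (shrink < 1)
        warning("rest template jitter clipped to preserve PSD")
      return(sig)
    }
  }
  tpl$sigma
}
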