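#' Generate hROI-level task contrasts for the synthetic cohort
#'
#' For every participant and task (PROD, LISN, READ sentence-minus-word-list
#' contrasts) a target network asymmetry is drawn per ROI set from the
#' group's calibrated mean/sd, and per-hROI left/right BOLD contrast values
#' are constructed so that the volume-weighted mean asymmetry recomputed by
#' [network_asymmetry()] reproduces the drawn targets exactly (to numerical
#' precision): hub pairs carry the SENT_HUBS target, non-hub pairs carry the
#' value required to meet the SENT_CORE target given the hub block, and
#' per-hROI noise is projected onto the zero-weighted-sum subspace of each
#' block so neither constraint moves.
#'
#' Planted dissociations: crossed ATYP participants get a production
#' asymmetry opposite in sign to listening/reading (majority: production
#' leftward, perception rightward; a minority reversed); crossed TYP_MILD
#' flip reading and crossed TYP_STRONG flip listening just past the
#' dissociation band. Congruent participants' targets are clamped out of
#' the opposite-direction region so the latent dissociation labels are a
#' coherent truth.
#'
#' @param cohort Participant table from [generate_cohort()].
#' @param atlas Atlas data frame, see [default_atlas()].
#' @param config A `cohort_config`.
#' @return Long `data.frame` (`participant_id`, `task`, `pair_name`,
#'   `hemisphere`, `bold`) covering the complete grid.
#' @export
generate_task_contrasts <- function(cohort, atlas,
                                    config = default_cohort_config()) {
  set.seed(stage_seed(config, "task"))
  tasks <- c("PROD", "LISN", "READ")
  pairs <- atlas_pairs(atlas)
  hubs <- sent_hubs(atlas)
  w_all <- pair_weights(atlas, "SENT_CORE")
  hub_sel <- names(w_all) %in% hubs
  w_hub <- w_all[hub_sel]
  w_non <- w_all[!hub_sel]

  n <- nrow(cohort)
  res <- vector("list", n * length(tasks))
  k <- 0L
  for (i in seq_len(n)) {
    g <- cohort$latent_group[i]
    diss <- cohort$latent_dissociation[i]
    sub <- cohort$latent_crossed_subtype[i]
    targ <- draw_asym_targets(g, diss, sub, config)
    for (task in tasks) {
      a_core <- targ[["SENT_CORE"]][[task]]
      a_hub <- targ[["SENT_HUBS"]][[task]]
      d <- numeric(length(pairs))
      d[hub_sel] <- a_hub
      d[!hub_sel] <- (a_core * sum(w_all) - a_hub * sum(w_hub)) / sum(w_non)
      if (config$task_roi_noise_sd > 0) {
        d[hub_sel] <- d[hub_sel] +
          zero_wsum_noise(w_hub, config$task_roi_noise_sd)
        d[!hub_sel] <- d[!hub_sel] +
          zero_wsum_noise(w_non, config$task_roi_noise_sd)
      }
      base <- stats::rnorm(length(pairs), config$task_base_mean,
                           config$task_base_sd)
      k <- k + 1L
      res[[k]] <- data.frame(
        participant_id = cohort$id[i], task = task,
        pair_name = rep(pairs, 2L),
        hemisphere = rep(c("L", "R"), each = length(pairs)),
        bold = c(base + d / 2, base - d / 2),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# noise with zero volume-weighted sum, so network asymmetries are untouched
zero_wsum_noise <- function(w, sd) {
  e <- stats::rnorm(length(w), 0, sd)
  e - w * sum(w * e) / sum(w * w)
}

# draw the six signed targets (2 roi sets x 3 tasks) for one participant
draw_asym_targets <- function(group, dissociation, subtype, config) {
  tasks <- c("PROD", "LISN", "READ")
  out <- list(SENT_CORE = list(), SENT_HUBS = list())
  for (rs in names(out)) {
    for (task in tasks) {
      p <- config$task_asym_params[[rs]][[task]][group, ]
      out[[rs]][[task]] <- stats::rnorm(1L, p[1L], p[2L])
    }
  }
  floor_ <- config$crossed_floor
  clamp <- config$congruent_clamp
  sgn_major <- if (group == "ATYP") -1 else 1  # majority direction of group
  if (dissociation == "CROSSED") {
    flip <- switch(subtype,
                   PROD_LEFT = c(PROD = 1, LISN = -1, READ = -1),
                   PROD_RIGHT = c(PROD = -1, LISN = 1, READ = 1),
                   READ_RIGHT = c(PROD = 1, LISN = 1, READ = -1),
                   LISN_RIGHT = c(PROD = 1, LISN = -1, READ = 1))
    for (rs in names(out)) for (task in tasks) {
      v <- out[[rs]][[task]]
      out[[rs]][[task]] <- flip[[task]] * max(abs(v), floor_)
    }
    if (group != "ATYP") {
      # typical dissociations are small rightward excursions on one task
      ft <- names(which(flip < 0))
      for (rs in names(out))
        out[[rs]][[ft]] <- -min(abs(out[[rs]][[ft]]), floor_ + 0.04)
    }
  } else {
    # keep congruent draws out of the opposite-direction band
    for (rs in names(out)) for (task in tasks) {
      v <- out[[rs]][[task]]
      if (sgn_major > 0) out[[rs]][[task]] <- max(v, -clamp)
      else out[[rs]][[task]] <- min(v, clamp)
    }
  }
  out
}
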