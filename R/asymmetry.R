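#' Volumetric-mean network asymmetry from hROI contrast values
#'
#' For the selected ROI set (all 18 pairs, SENT_CORE, or the 3 hub pairs,
#' SENT_HUBS), forms the per-pair left-minus-right BOLD contrast
#' difference and returns the volume-weighted mean
#' \deqn{A = \sum_i w_i (L_i - R_i) / \sum_i w_i,}
#' where the pair weight \eqn{w_i} is the sum of the pair's left and right
#' hROI volumes (symmetric under hemisphere exchange, so swapping all L/R
#' values negates the asymmetry). Positive values indicate leftward
#' lateralization.
#'
#' @param contrasts Long contrast table (`participant_id`, `task`,
#'   `pair_name`, `hemisphere`, `bold`).
#' @param atlas Atlas data frame.
#' @param roi_set `"SENT_CORE"` or `"SENT_HUBS"`.
#' @param participant,task Cell to compute.
#' @return Scalar asymmetry (dimensionless).
#' @export
network_asymmetry <- function(contrasts, atlas,
                              roi_set = c("SENT_CORE", "SENT_HUBS"),
                              participant, task) {
  roi_set <- match.arg(roi_set)
  sub <- contrasts[contrasts$participant_id == participant &
                     contrasts$task == task, , drop = FALSE]
  w <- pair_weights(atlas, roi_set)
  l <- sub$bold[match(paste(names(w), "L"),
                      paste(sub$pair_name, sub$hemisphere))]
  r <- sub$bold[match(paste(names(w), "R"),
                      paste(sub$pair_name, sub$hemisphere))]
  if (anyNA(l) || anyNA(r)) {
    miss <- names(w)[is.na(l) | is.na(r)][1L]
    stop("missing contrast cell for participant ", participant,
         ", task ", task, ", hROI ", miss)
  }
  sum(w * (l - r)) / sum(w)
}

#' Asymmetry profiles for a whole cohort
#'
#' Vectorizes [network_asymmetry()] over participants, tasks (PROD, LISN,
#' READ) and ROI sets, returning one row per participant with the six
#' signed asymmetries (columns `CORE_PROD`, `CORE_LISN`, `CORE_READ`,
#' `HUBS_PROD`, `HUBS_LISN`, `HUBS_READ`, in this fixed order) and the six
#' absolute values (`ABS_` prefix).
#'
#' @inheritParams network_asymmetry
#' @return `data.frame` with `id` plus 12 asymmetry columns.
#' @export
asymmetry_profiles <- function(contrasts, atlas) {
  tasks <- c("PROD", "LISN", "READ")
  ids <- unique(contrasts$participant_id)
  w_core <- pair_weights(atlas, "SENT_CORE")
  w_hubs <- pair_weights(atlas, "SENT_HUBS")
  # complete-grid check, then fast array computation
  key <- paste(contrasts$participant_id, contrasts$task,
               contrasts$pair_name, contrasts$hemisphere)
  if (anyDuplicated(key)) stop("duplicate contrast rows: ",
                               key[duplicated(key)][1L])
  expected <- length(ids) * length(tasks) * 2L * length(w_core)
  if (nrow(contrasts) != expected)
    stop("incomplete contrast grid: ", nrow(contrasts), " rows, expected ",
         expected)
  if (!all(is.finite(contrasts$bold))) stop("non-finite contrast values")
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (rs in c("CORE", "HUBS")) {
    w <- if (rs == "CORE") w_core else w_hubs
    for (task in tasks) {
      sub <- contrasts[contrasts$task == task &
                         contrasts$pair_name %in% names(w), ]
      l <- sub[sub$hemisphere == "L", ]
      r <- sub[sub$hemisphere == "R", ]
      dl <- l$bold[order(match(l$participant_id, ids),
                         match(l$pair_name, names(w)))]
      dr <- r$bold[order(match(r$participant_id, ids),
                         match(r$pair_name, names(w)))]
      d <- matrix(dl - dr, nrow = length(w))  # pairs x participants
      out[[paste(rs, task, sep = "_")]] <- colSums(d * w) / sum(w)
    }
  }
  for (cn in setdiff(names(out), "id"))
    out[[paste0("ABS_", cn)]] <- abs(out[[cn]])
  out
}
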