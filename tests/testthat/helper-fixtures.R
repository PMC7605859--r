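# Shared fixtures and small oracles, all built in code.

# tiny atlas with a configurable number of pairs (first pair is a hub)
tiny_atlas <- function(volumes_l, volumes_r = volumes_l,
                       pair_names = paste0("P", seq_along(volumes_l)),
                       hub_pairs = pair_names[1L]) {
  df <- data.frame(
    pair_name = rep(pair_names, 2L),
    hemisphere = rep(c("L", "R"), each = length(pair_names)),
    volume_mm3 = c(volumes_l, volumes_r),
    is_hub = rep(pair_names %in% hub_pairs, 2L))
  validate_atlas(df, n_pairs = length(pair_names), hubs = NULL)
}

# long-format contrast table from per-pair L/R value vectors
contrast_table <- function(atlas, l, r, participant = "S1", task = "PROD") {
  pairs <- atlas_pairs(atlas)
  data.frame(participant_id = participant, task = task,
             pair_name = rep(pairs, 2L),
             hemisphere = rep(c("L", "R"), each = length(pairs)),
             bold = c(l, r), stringsAsFactors = FALSE)
}

# named correlation matrix for an n-pair atlas from blocks
named_corr <- function(atlas, mat) {
  pairs <- atlas_pairs(atlas)
  cn <- c(paste0(pairs, "_L"), paste0(pairs, "_R"))
  dimnames(mat) <- list(cn, cn)
  mat
}

# exhaustive Ward oracle: greedy minimum within-cluster-variance increase
ward_oracle_partitions <- function(x) {
  clusters <- as.list(seq_len(nrow(x)))
  parts <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_cost <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        a <- clusters[[i]]; b <- clusters[[j]]
        ma <- colMeans(x[a, , drop = FALSE])
        mb <- colMeans(x[b, , drop = FALSE])
        cost <- length(a) * length(b) / (length(a) + length(b)) *
          sum((ma - mb)^2)
        if (cost < best_cost - 1e-12) { best_cost <- cost; best <- c(i, j) }
      }
    }
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
    lab <- integer(nrow(x))
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    parts[[length(parts) + 1L]] <- lab
  }
  parts  # partitions at k = n-1, ..., 1
}

# truth-table oracle for the dissociation rule (both_poles)
dissociation_oracle <- function(a, threshold = 0.05) {
  lab <- function(v) ifelse(v >= threshold, "L",
                            ifelse(v <= -threshold, "R", "N"))
  core <- lab(a[1:3]); hubs <- lab(a[4:6])
  crossed <- (any(core == "L") && any(core == "R")) ||
    (any(hubs == "L") && any(hubs == "R"))
  if (crossed) "CROSSED" else "CONGRUENT"
}

# hand-formula adjusted Rand index
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  nt <- comb2(sum(tab))
  exp_ <- si * sj / nt
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# cached default-cohort classification runs shared across tests
.cohort_cache <- new.env(parent = emptyenv())
cohort_classification_run <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cfg <- default_cohort_config(seed = seed)
  coh <- generate_cohort(cfg)
  atl <- default_atlas()
  ct <- generate_task_contrasts(coh, atl, cfg)
  prof <- asymmetry_profiles(ct, atl)
  rest <- suppressWarnings(generate_rest_timeseries(coh, atl, cfg))
  met <- connectivity_metrics(rest, atl)
  fz <- build_features(prof, met, standardize = TRUE)
  tree <- ward_tree(fz)
  sel <- select_k(fz, tree)
  fr <- build_features(prof, met)
  grp <- suppressWarnings(assign_groups(fr, tree, 3L))
  res <- list(config = cfg, cohort = coh, profiles = prof, metrics = met,
              selection = sel, groups = grp)
  .cohort_cache[[key]] <- res
  res
}
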