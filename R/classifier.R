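#' Assemble the nine-variable clustering feature matrix
#'
#' Joins the task-asymmetry profiles and resting-state connectivity
#' metrics into the fixed-order feature matrix used for phenotype
#' clustering: `CORE_PROD`, `CORE_LISN`, `CORE_READ`, `HUBS_PROD`,
#' `HUBS_LISN`, `HUBS_READ`, `rs_dc_sum`, `rs_dc_asym`, `mihhc`
#' (homotopic correlation on the r scale; standardization makes the r/z
#' choice irrelevant for clustering).
#'
#' @param profiles Output of [asymmetry_profiles()].
#' @param metrics Output of [connectivity_metrics()].
#' @param standardize Z-score each column (sample mean/sd)?
#' @return Numeric matrix (rownames = participant ids) with attributes
#'   `standardized`, and `center`/`scale` when standardized.
#' @export
build_features <- function(profiles, metrics, standardize = FALSE) {
  if (!setequal(profiles$id, metrics$id))
    stop("participant ids differ between profiles and metrics: ",
         paste(utils::head(c(setdiff(profiles$id, metrics$id),
                             setdiff(metrics$id, profiles$id)), 5L),
               collapse = ", "))
  metrics <- metrics[match(profiles$id, metrics$id), ]
  x <- cbind(as.matrix(profiles[, c("CORE_PROD", "CORE_LISN", "CORE_READ",
                                    "HUBS_PROD", "HUBS_LISN", "HUBS_READ")]),
             rs_dc_sum = metrics$rs_dc_sum,
             rs_dc_asym = metrics$rs_dc_asym,
             mihhc = metrics$mihhc_r)
  rownames(x) <- profiles$id
  if (anyNA(x)) stop("missing values in feature matrix")
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance feature column: ",
           colnames(x)[which(sds == 0)[1L]])
    ctr <- colMeans(x)
    x <- scale(x, center = ctr, scale = sds)
    attr(x, "center") <- ctr
    attr(x, "scale") <- sds
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
  }
  attr(x, "standardized") <- standardize
  x
}

#' Ward agglomeration of the standardized feature matrix
#'
#' Hierarchical clustering with the Ward minimum-variance criterion on
#' Euclidean distances (the `ward.D2` form of `hclust`, which operates on
#' distances, not squared distances). Merge heights are non-decreasing.
#'
#' @param features Standardized feature matrix from [build_features()].
#' @return An `hclust` tree.
#' @export
ward_tree <- function(features) {
  if (anyNA(features)) stop("NA in feature matrix")
  if (nrow(features) < 2L) stop("need at least 2 rows")
  stats::hclust(stats::dist(features, method = "euclidean"),
                method = "ward.D2")
}

#' Select the number of clusters by validity-index majority vote
#'
#' Cuts the Ward tree at each candidate k and lets each internal validity
#' index vote for the k at which it is optimal; the modal k wins, with
#' ties broken towards the smallest k. The default panel of 12 indices:
#' Calinski-Harabasz, mean silhouette, Davies-Bouldin, Dunn, C-index,
#' McClain-Rao, point-biserial, PBM, gap statistic (uniform reference,
#' first-SE-max rule), Xie-Beni, Ratkowsky-Lance and the Ball-Hall
#' successive-difference criterion.
#'
#' @param features Standardized feature matrix.
#' @param tree `hclust` tree from [ward_tree()]; recomputed if `NULL`.
#' @param k_range Candidate cluster counts (default 2:8).
#' @param index_set Character vector naming the indices to use.
#' @param gap_b Number of uniform reference data sets for the gap
#'   statistic.
#' @return List with `k` (selected), `votes` (named integer vector, one
#'   vote per index) and `values` (index x k matrix of criterion values).
#' @export
select_k <- function(features, tree = NULL, k_range = 2:8,
                     index_set = validity_indices(), gap_b = 20L) {
  n <- nrow(features)
  if (min(k_range) < 2L || max(k_range) > n - 1L)
    stop("k_range must lie within [2, n-1]")
  if (is.null(tree)) tree <- ward_tree(features)
  d <- stats::dist(features)
  labels <- lapply(k_range, function(k) stats::cutree(tree, k))
  names(labels) <- k_range
  vals <- matrix(NA_real_, length(index_set), length(k_range),
                 dimnames = list(index_set, k_range))
  for (idx in setdiff(index_set, c("gap", "ball_hall"))) {
    vals[idx, ] <- vapply(labels, function(lab)
      validity_index(idx, features, lab, d), numeric(1))
  }
  votes <- integer(0)
  maximize <- c(calinski_harabasz = TRUE, silhouette = TRUE,
                davies_bouldin = FALSE, dunn = TRUE, c_index = FALSE,
                mcclain_rao = FALSE, point_biserial = TRUE, pbm = TRUE,
                xie_beni = FALSE, ratkowsky_lance = TRUE)
  for (idx in intersect(index_set, names(maximize))) {
    v <- vals[idx, ]
    best <- if (maximize[[idx]]) which.max(v) else which.min(v)
    votes[idx] <- k_range[best]  # which.max/min take the first (smallest k) tie
  }
  if ("ball_hall" %in% index_set) {
    # mean within-cluster SS per cluster, including k = 1; vote at the
    # largest drop between successive levels
    wk <- vapply(c(1L, k_range), function(k) {
      lab <- if (k == 1L) rep(1L, n) else labels[[as.character(k)]]
      wgss(features, lab) / k
    }, numeric(1))
    drops <- -diff(wk)
    vals["ball_hall", ] <- drops
    votes["ball_hall"] <- k_range[which.max(drops)]
  }
  if ("gap" %in% index_set) {
    g <- gap_statistic(features, k_range, b = gap_b)
    vals["gap", ] <- g$gap
    votes["gap"] <- g$k
  }
  tab <- table(factor(votes, levels = sort(unique(k_range))))
  k <- as.integer(names(tab)[which.max(tab)])  # smallest k on ties
  list(k = k, votes = votes, values = vals)
}

#' @rdname select_k
#' @export
validity_indices <- function() {
  c("calinski_harabasz", "silhouette", "davies_bouldin", "dunn", "c_index",
    "mcclain_rao", "point_biserial", "pbm", "gap", "xie_beni",
    "ratkowsky_lance", "ball_hall")
}

# total within-cluster sum of squares
wgss <- function(x, lab) {
  sum(vapply(split(seq_len(nrow(x)), lab), function(ix) {
    xs <- x[ix, , drop = FALSE]
    sum(sweep(xs, 2L, colMeans(xs))^2)
  }, numeric(1)))
}

cluster_centroids <- function(x, lab) {
  cs <- vapply(split(seq_len(nrow(x)), lab),
               function(ix) colMeans(x[ix, , drop = FALSE]),
               numeric(ncol(x)))
  t(cs)  # k x p
}

# single internal validity index value for one partition
validity_index <- function(name, x, lab, d = stats::dist(x)) {
  n <- nrow(x)
  k <- length(unique(lab))
  dm <- as.matrix(d)
  cent <- cluster_centroids(x, lab)
  sizes <- as.vector(table(lab))
  w <- wgss(x, lab)
  tot <- sum(sweep(x, 2L, colMeans(x))^2)
  b <- tot - w
  same <- outer(lab, lab, "==")
  ut <- upper.tri(dm)
  dw <- dm[ut & same]     # within-cluster pairwise distances
  db <- dm[ut & !same]    # between-cluster pairwise distances
  switch(name,
    calinski_harabasz = (b / (k - 1)) / (w / (n - k)),
    silhouette = mean(cluster::silhouette(lab, d)[, "sil_width"]),
    davies_bouldin = {
      s <- vapply(seq_len(k), function(i)
        mean(sqrt(rowSums(sweep(x[lab == i, , drop = FALSE], 2L,
                                cent[i, ])^2))), numeric(1))
      mean(vapply(seq_len(k), function(i)
        max(vapply(setdiff(seq_len(k), i), function(j)
          (s[i] + s[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2)),
          numeric(1))), numeric(1)))
    },
    dunn = min(db) / max(dw),
    c_index = {
      nw <- length(dw)
      ds <- sort(dm[ut])
      smin <- sum(ds[seq_len(nw)])
      smax <- sum(ds[seq.int(length(ds) - nw + 1L, length(ds))])
      (sum(dw) - smin) / (smax - smin)
    },
    mcclain_rao = mean(dw) / mean(db),
    point_biserial = {
      dv <- dm[ut]
      nw <- length(dw); nb <- length(db); nt <- nw + nb
      (mean(db) - mean(dw)) * sqrt(nw * nb / nt^2) / stats::sd(dv)
    },
    pbm = {
      e1 <- sum(sqrt(rowSums(sweep(x, 2L, colMeans(x))^2)))
      ek <- sum(sqrt(rowSums((x - cent[lab, , drop = FALSE])^2)))
      dk <- max(stats::dist(cent))
      ((e1 * dk) / (k * ek))^2
    },
    xie_beni = {
      mind2 <- min(stats::dist(cent)^2)
      sum((x - cent[lab, , drop = FALSE])^2) / (n * mind2)
    },
    ratkowsky_lance = {
      bj <- vapply(seq_len(ncol(x)), function(j) {
        mj <- mean(x[, j])
        bgss_j <- sum(sizes * (cent[, j] - mj)^2)
        tss_j <- sum((x[, j] - mj)^2)
        bgss_j / tss_j
      }, numeric(1))
      mean(sqrt(bj)) / sqrt(k)
    },
    stop("unknown validity index: ", name)
  )
}

# Tibshirani gap statistic on hierarchical Ward clustering, uniform
# reference over the range of each (PCA-rotated) feature; vote by the
# first-SE-max rule, falling back to the global maximum
gap_statistic <- function(x, k_range, b = 20L) {
  n <- nrow(x)
  sv <- svd(sweep(x, 2L, colMeans(x)), nu = 0)
  xr <- sweep(x, 2L, colMeans(x)) %*% sv$v  # rotate to principal axes
  rng <- apply(xr, 2L, range)
  logw <- function(z) {
    tr <- stats::hclust(stats::dist(z), method = "ward.D2")
    vapply(k_range, function(k) log(wgss(z, stats::cutree(tr, k))),
           numeric(1))
  }
  obs <- logw(x)
  ref <- replicate(b, {
    z <- vapply(seq_len(ncol(xr)), function(j)
      stats::runif(n, rng[1L, j], rng[2L, j]), numeric(n))
    logw(z %*% t(sv$v))
  })
  gap <- rowMeans(ref) - obs
  se <- apply(ref, 1L, stats::sd) * sqrt(1 + 1 / b)
  k_sel <- NA_integer_
  for (i in seq_len(length(k_range) - 1L)) {
    if (gap[i] >= gap[i + 1L] - se[i + 1L]) { k_sel <- k_range[i]; break }
  }
  if (is.na(k_sel)) k_sel <- k_range[which.max(gap)]
  list(k = k_sel, gap = gap, se = se)
}

#' Label the clusters as lateralization phenotypes
#'
#' For k = 3, the cluster with the lowest mean over the six task-asymmetry
#' features is ATYP (atypical, rightward-mean organization; the label is
#' suffixed `_unverified` with a warning if that mean is not negative); of
#' the remaining two, the cluster with the higher mean `CORE_PROD`
#' asymmetry is TYP_STRONG and the other TYP_MILD. Other k get generic
#' labels `cluster_1..k` with a warning.
#'
#' @param features Unstandardized feature matrix from [build_features()].
#' @param tree `hclust` tree.
#' @param k Number of clusters.
#' @return `data.frame` with `id`, `cluster_id`, `group`.
#' @export
assign_groups <- function(features, tree, k = 3L) {
  lab <- stats::cutree(tree, k)
  ids <- rownames(features)
  if (k != 3L) {
    warning("k != 3: using generic cluster labels")
    return(data.frame(id = ids, cluster_id = lab,
                      group = paste0("cluster_", lab),
                      stringsAsFactors = FALSE))
  }
  task_cols <- c("CORE_PROD", "CORE_LISN", "CORE_READ",
                 "HUBS_PROD", "HUBS_LISN", "HUBS_READ")
  cm <- vapply(1:3, function(cl)
    mean(features[lab == cl, task_cols]), numeric(1))
  atyp <- which.min(cm)
  rest <- setdiff(1:3, atyp)
  prod_m <- vapply(rest, function(cl)
    mean(features[lab == cl, "CORE_PROD"]), numeric(1))
  strong <- rest[which.max(prod_m)]
  mild <- setdiff(rest, strong)
  names <- character(3)
  names[atyp] <- "ATYP"; names[strong] <- "TYP_STRONG"; names[mild] <- "TYP_MILD"
  if (cm[atyp] >= 0) {
    warning("lowest-asymmetry cluster has non-negative mean asymmetry; ",
            "labels marked _unverified")
    names <- paste0(names, "_unverified")
  }
  data.frame(id = ids, cluster_id = lab, group = names[lab],
             stringsAsFactors = FALSE)
}

#' Classify dissociated (crossed) lateralization
#'
#' Each of the six signed asymmetries gets a direction label: `L` if
#' >= +threshold, `R` if <= -threshold, else `N` (neutral band). A
#' participant is CROSSED if, within at least one ROI set (SENT_CORE or
#' SENT_HUBS), the three task labels contain both an `L` and an `R`
#' (`rule = "both_poles"`, default: a task inside the neutral band never
#' triggers a dissociation). With `rule = "one_pole"` a single
#' supra-threshold task opposing the sign of any other task (including
#' sub-threshold ones of opposite sign) counts.
#'
#' @param profiles Output of [asymmetry_profiles()] (or any data frame
#'   with the six signed columns).
#' @param threshold Dissociation band half-width (default 0.05).
#' @param rule `"both_poles"` or `"one_pole"`.
#' @return `data.frame` with `id`, six direction-label columns
#'   (`DIR_<set>_<task>`) and `dissociation`.
#' @export
classify_dissociation <- function(profiles, threshold = 0.05,
                                  rule = c("both_poles", "one_pole")) {
  rule <- match.arg(rule)
  cols <- list(CORE = c("CORE_PROD", "CORE_LISN", "CORE_READ"),
               HUBS = c("HUBS_PROD", "HUBS_LISN", "HUBS_READ"))
  lab_one <- function(a)
    ifelse(a >= threshold, "L", ifelse(a <= -threshold, "R", "N"))
  out <- data.frame(id = profiles$id, stringsAsFactors = FALSE)
  crossed <- rep(FALSE, nrow(profiles))
  for (rs in names(cols)) {
    labs <- vapply(cols[[rs]], function(cn) lab_one(profiles[[cn]]),
                   character(nrow(profiles)))
    labs <- matrix(labs, nrow = nrow(profiles),
                   dimnames = list(NULL, paste0("DIR_", cols[[rs]])))
    out <- cbind(out, as.data.frame(labs, stringsAsFactors = FALSE))
    if (rule == "both_poles") {
      crossed <- crossed |
        (rowSums(labs == "L") > 0 & rowSums(labs == "R") > 0)
    } else {
      signs <- sign(as.matrix(profiles[, cols[[rs]]]))
      crossed <- crossed |
        (rowSums(labs == "L") > 0 & rowSums(signs < 0) > 0) |
        (rowSums(labs == "R") > 0 & rowSums(signs > 0) > 0)
    }
  }
  out$dissociation <- ifelse(crossed, "CROSSED", "CONGRUENT")
  out
}
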