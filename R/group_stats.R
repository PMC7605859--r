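#' Residualize scores on covariates
#'
#' Ordinary least-squares residuals of each score column after regression
#' on the requested covariates plus an intercept. Categorical covariates
#' (character or factor columns) are dummy-coded. With an empty covariate
#' set the scores are simply mean-centered.
#'
#' @param scores Data frame or matrix of numeric score columns.
#' @param covariates Data frame of covariates (rows aligned with
#'   `scores`).
#' @param covariate_set Character vector of covariate column names to
#'   use; default all columns of `covariates`.
#' @return Data frame of residuals, same column names as `scores`.
#' @export
residualize <- function(scores, covariates = NULL,
                        covariate_set = colnames(covariates)) {
  y <- as.matrix(scores)
  n <- nrow(y)
  if (is.null(covariates) || length(covariate_set) == 0L) {
    return(as.data.frame(sweep(y, 2L, colMeans(y))))
  }
  covariates <- as.data.frame(covariates)[, covariate_set, drop = FALSE]
  x <- stats::model.matrix(~ ., data = covariates)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    stop("singular covariate design; collinear columns: ",
         paste(colnames(x)[-keep], collapse = ", "))
  }
  as.data.frame(y - x %*% qr.coef(qx, y))
}

#' Repeated-measures MANOVA (multivariate approach)
#'
#' Fits a multivariate linear model of the within-participant measures on
#' the between-participant factors and reports Pillai's trace tests
#' (Type III sums of squares, sum-to-zero contrasts) for each
#' between-factor main effect and interaction, the within factor(s), and
#' all within-by-between interactions, using the multivariate approach to
#' repeated measures on difference contrasts.
#'
#' @param dep Matrix or data frame, one column per within-participant
#'   cell (e.g. one per task), rows = participants.
#' @param between Data frame of between-participant factors.
#' @param within Data frame describing the within structure: one row per
#'   column of `dep`, factor columns (e.g. `task`).
#' @return `data.frame` (effect, statistic kind, value, df1, df2, F,
#'   p-value): the effect table.
#' @export
repeated_manova <- function(dep, between, within) {
  dep <- as.matrix(dep)
  if (anyNA(dep)) stop("missing within-participant cells")
  between <- as.data.frame(between)
  between[] <- lapply(between, function(c)
    if (is.character(c)) factor(c) else c)
  within <- as.data.frame(within)
  within[] <- lapply(within, function(c)
    if (is.character(c)) factor(c) else c)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fml <- stats::as.formula(paste(
    "dep ~", paste(colnames(between), collapse = " * ")))
  fit <- stats::lm(fml, data = between)
  idesign <- stats::as.formula(paste(
    "~", paste(colnames(within), collapse = " * ")))
  av <- car::Anova(fit, idata = within, idesign = idesign, type = "III",
                   test.statistic = "Pillai")
  sm <- summary(av, multivariate = TRUE, univariate = FALSE)
  rows <- lapply(names(sm$multivariate.tests), function(term) {
    tst <- sm$multivariate.tests[[term]]
    st <- tryCatch({
      # Pillai trace and its F approximation from the hypothesis and
      # error SSP matrices
      H <- tst$SSPH; E <- tst$SSPE
      ev <- Re(eigen(qr.solve(E + H, H), only.values = TRUE)$values)
      pillai <- sum(ev)
      s <- min(tst$df, ncol(H))
      m <- 0.5 * (abs(tst$df - ncol(H)) - 1)
      nn <- 0.5 * (tst$df.residual - ncol(H) - 1)
      df1 <- s * (2 * m + s + 1)
      df2 <- s * (2 * nn + s + 1)
      f <- (pillai / (s - pillai)) * (df2 / df1)
      p <- stats::pf(f, df1, df2, lower.tail = FALSE)
      c(pillai, df1, df2, f, p)
    }, error = function(e) rep(NA_real_, 5L))
    data.frame(effect = term, statistic = "Pillai", value = st[1L],
               df1 = st[2L], df2 = st[3L], F = st[4L], p_value = st[5L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$effect != "(Intercept)", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range adjusted pairwise group comparisons after a one-way
#' ANOVA.
#'
#' @param values Numeric vector.
#' @param group Factor (or coercible) of group membership.
#' @return `data.frame` (group_a, group_b, diff, lwr, upr, p_adj) with
#'   one row per unordered pair.
#' @export
tukey_hsd <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L))
    stop("group with fewer than 2 observations: ",
         names(which(table(group) < 2L))[1L])
  fit <- stats::aov(values ~ group)
  tk <- stats::TukeyHSD(fit)$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group_a = vapply(pairs, `[`, "", 1L),
             group_b = vapply(pairs, `[`, "", 2L),
             diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = tk[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pearson chi-square proportion test
#'
#' Chi-square test of homogeneity/independence on a contingency table,
#' without continuity correction; df = (r-1)(c-1).
#'
#' @param counts Matrix of non-negative integer counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
proportion_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all-zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' PCA with promax rotation and scree-based retention
#'
#' Principal components of the correlation matrix of (residualized)
#' scores. The number of retained components is chosen by the scree
#' criterion, operationalized as the elbow of the eigenvalue profile via
#' the maximal second difference (acceleration): the elbow at position j
#' retains j - 1 components. The elbow is only trusted when the spectrum
#' levels off into a numerically null tail beyond it (effectively
#' low-rank data); otherwise there is no unique elbow and the Kaiser
#' rule (eigenvalue > 1) is used instead. Retained
#' components are promax-rotated (power 4 by default). Variance explained
#' is reported pre-rotation.
#'
#' @param residuals `n x p` data frame/matrix of residualized scores.
#' @param retain `"scree"` or a fixed integer number of components.
#' @param promax_power Power of the promax rotation.
#' @return List of class `pca_promax`: `n_components`, `eigenvalues`,
#'   `variance_explained` (% per retained component, pre-rotation),
#'   `loadings` (p x k, rotated), `scores` (n x k, regression method),
#'   `retention_rule`.
#' @export
pca_promax <- function(residuals, retain = "scree", promax_power = 4) {
  x <- as.matrix(residuals)
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("need more observations than variables")
  r <- stats::cor(x)
  ei <- eigen(r, symmetric = TRUE)
  ev <- ei$values
  if (identical(retain, "scree")) {
    k <- scree_ncomp(ev)
    rule <- attr(k, "rule")
  } else {
    k <- as.integer(retain)
    if (k < 1L || k > p) stop("retain must be in [1, ", p, "]")
    rule <- "fixed"
  }
  raw <- ei$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k, k)
  rownames(raw) <- colnames(x)
  if (k > 1L) {
    load <- tryCatch(unclass(stats::promax(raw, m = promax_power)$loadings),
                     error = function(e) {
                       warning("promax rotation failed (degenerate ",
                               "loadings); returning unrotated components")
                       raw
                     })
  } else {
    load <- raw
  }
  colnames(load) <- paste0("PC", seq_len(k))
  z <- scale(x)
  scores <- z %*% MASS::ginv(r) %*% load  # regression-method factor scores
  list(n_components = as.integer(k), eigenvalues = ev,
       variance_explained = 100 * ev[seq_len(k)] / p,
       loadings = load, scores = scores, retention_rule = rule)
}

# Scree elbow by maximal acceleration (second difference). An elbow is
# only unambiguous when the spectrum levels off into a numerically null
# tail (effectively low-rank data); smoothly declining spectra, which
# noisy batteries produce, have no unique elbow — automated elbow
# detection is then unstable — and retention falls back to the Kaiser
# rule (eigenvalue > 1), the classic default for this decision.
scree_ncomp <- function(ev, null_tail = 0.1) {
  p <- length(ev)
  acc <- ev[seq_len(p - 2L) + 2L] - 2 * ev[seq_len(p - 2L) + 1L] +
    ev[seq_len(p - 2L)]  # acceleration at positions 2..p-1
  if (length(acc) >= 1L && max(acc) > 1e-12) {
    elbow <- which.max(acc) + 1L  # eigenvalue index of maximal curvature
    if (mean(ev[elbow:p]) < null_tail) {
      k <- max(1L, elbow - 1L)
      attr(k, "rule") <- "scree"
      return(k)
    }
  }
  k <- max(1L, sum(ev > 1))
  attr(k, "rule") <- "kaiser"
  k
}

#' Anatomy comparison: asymmetries and corpus callosum
#'
#' Residualizes gray-matter asymmetry (GMasym = left - right), white
#' matter asymmetry (WMasym) and corpus-callosum volume (CCvol) on the
#' covariates, then (1) runs a repeated-measures ANOVA over the tissue
#' compartment (gray/white) with organization (TYP = TYP_STRONG +
#' TYP_MILD merged, vs ATYP) and dissociation (CROSSED/CONGRUENT) as
#' between factors, and (2) a factorial ANOVA of CCvol residuals with the
#' organization x dissociation interaction.
#'
#' @param anatomy Output of [generate_anatomy()] (or same columns).
#' @param labels Data frame with `id`, `group`
#'   (TYP_STRONG/TYP_MILD/ATYP or TYP/ATYP), `dissociation`.
#' @param covariates Optional data frame (aligned on `id`) of covariates,
#'   e.g. age, sex, handedness, total brain volume; `NULL` for the
#'   covariate-free analysis.
#' @return List with `asym_effects` (effect table of the repeated-measures
#'   ANOVA), `cc_effects` (CCvol ANOVA effect table), `cc_posthoc`
#'   (Tukey HSD on the four organization x dissociation cells).
#' @export
anatomy_comparison <- function(anatomy, labels, covariates = NULL) {
  stopifnot(all(anatomy$id %in% labels$id))
  labels <- labels[match(anatomy$id, labels$id), ]
  org <- factor(ifelse(labels$group == "ATYP", "ATYP", "TYP"))
  diss <- factor(labels$dissociation)
  y <- cbind(GMasym = anatomy$gm_left - anatomy$gm_right,
             WMasym = anatomy$wm_left - anatomy$wm_right,
             CCvol = anatomy$cc_volume)
  if (!is.null(covariates)) {
    cv <- covariates[match(anatomy$id, covariates$id), , drop = FALSE]
    cv$id <- NULL
    y <- as.matrix(residualize(y, cv))
  } else {
    y <- sweep(y, 2L, colMeans(y))
  }
  between <- data.frame(organization = org, dissociation = diss)
  asym <- repeated_manova(y[, c("GMasym", "WMasym")], between,
                          data.frame(compartment = c("gm", "wm")))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  cc_fit <- stats::lm(y[, "CCvol"] ~ org * diss)
  cc_av <- car::Anova(cc_fit, type = "III")
  cc <- data.frame(effect = rownames(cc_av), statistic = "F",
                   value = cc_av[["F value"]], df1 = cc_av$Df,
                   df2 = cc_av$Df[nrow(cc_av)],
                   p_value = cc_av[["Pr(>F)"]],
                   stringsAsFactors = FALSE)
  cc <- cc[!cc$effect %in% c("(Intercept)", "Residuals"), , drop = FALSE]
  rownames(cc) <- NULL
  cell <- interaction(org, diss, sep = "_")
  list(asym_effects = asym, cc_effects = cc,
       cc_posthoc = tukey_hsd(y[, "CCvol"], cell))
}
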