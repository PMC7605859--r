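#' Cross-tabulate two classifications
#'
#' Full contingency table of two categorical labelings on their shared
#' ids, with margins, row-conditional percentages and the adjusted Rand
#' index. For a constant labeling the ARI is undefined by the strict
#' formula and is reported as 0 with a warning.
#'
#' @param labels_a,labels_b Named vectors (names = participant ids) or
#'   plain vectors of equal length.
#' @return List with `table` (r x c contingency), `margins`,
#'   `row_percent` (conditional % of each row category falling in each
#'   column category), `ari`, `n`.
#' @export
cross_tabulate <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    shared <- intersect(names(labels_a), names(labels_b))
    if (length(shared) == 0L) stop("no shared participant ids")
    labels_a <- labels_a[shared]; labels_b <- labels_b[shared]
  } else if (length(labels_a) != length(labels_b)) {
    stop("unnamed labelings must have equal length")
  }
  keep <- !is.na(labels_a) & !is.na(labels_b)
  labels_a <- labels_a[keep]; labels_b <- labels_b[keep]
  if (length(labels_a) == 0L) stop("no jointly labeled participants")
  tab <- table(labels_a, labels_b)
  if (length(unique(labels_a)) < 2L || length(unique(labels_b)) < 2L) {
    warning("constant labeling: adjusted Rand index reported as 0")
    ari <- 0
  } else {
    ari <- mclust::adjustedRandIndex(labels_a, labels_b)
  }
  list(table = tab,
       margins = list(rows = rowSums(tab), cols = colSums(tab)),
       row_percent = 100 * prop.table(tab, margin = 1L),
       ari = ari, n = length(labels_a))
}

#' Flow table for alluvial-style comparison of classifications
#'
#' One row per observed combination of the label columns with its count
#' (counts sum to the number of participants), optionally stratified by
#' an extra column (e.g. handedness, as in separate right-hander and
#' left-hander plots).
#'
#' @param labels Data frame containing the label columns.
#' @param columns Ordered character vector (>= 2) of label column names,
#'   one per alluvial axis.
#' @param stratify_by Optional column name to stratify the flows by.
#' @return `data.frame` of label combinations plus `count`.
#' @export
alluvial_table <- function(labels, columns, stratify_by = NULL) {
  if (length(columns) < 2L) stop("need at least 2 label columns")
  miss <- setdiff(c(columns, stratify_by), names(labels))
  if (length(miss)) stop("missing label columns: ",
                         paste(miss, collapse = ", "))
  cols <- c(stratify_by, columns)
  agg <- stats::aggregate(list(count = rep(1L, nrow(labels))),
                          by = labels[, cols, drop = FALSE], FUN = sum)
  out <- agg[do.call(order, agg[, cols, drop = FALSE]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Synthetic external classification labels
#'
#' Builds Gaussian-mixture-style (TYP/AMB/SA) and per-hemisphere SVM
#' dominance labels consistent with the published cross-classification
#' counts, for exercising the concordance analyses without the original
#' labelings: 9 SA members inside ATYP; 15 further ATYP members labeled
#' AMB, the remaining 6 ATYP labeled TYP; 16 TYP_MILD and 6 TYP_STRONG
#' members labeled AMB; everyone else TYP. SVM right-hemisphere dominance
#' is assigned to 17 ATYP and 5 TYP members (22 total).
#'
#' @param groups Data frame with `id` and `group` columns (the
#'   multitask-multimodal classification).
#' @param seed Integer seed for the (quota-exact) random assignment.
#' @return `data.frame` with `id`, `gmm_label`, `svm_left`, `svm_right`.
#' @export
synthetic_external_labels <- function(groups, seed = 1L) {
  set.seed(seed)
  n <- nrow(groups)
  gmm <- rep("TYP", n)
  atyp <- which(groups$group == "ATYP")
  mild <- which(groups$group == "TYP_MILD")
  strong <- which(groups$group == "TYP_STRONG")
  take <- function(idx, k) if (k >= length(idx)) idx
          else sample(idx, min(k, length(idx)))
  sa <- take(atyp, 9L)
  amb_a <- take(setdiff(atyp, sa), 15L)
  gmm[sa] <- "SA"; gmm[amb_a] <- "AMB"
  gmm[take(mild, 16L)] <- "AMB"
  gmm[take(strong, 6L)] <- "AMB"
  svm_right <- rep("NONDOM", n)
  rdom_a <- take(atyp, 17L)
  rdom_t <- take(c(mild, strong), 5L)
  svm_right[c(rdom_a, rdom_t)] <- "DOM"
  svm_left <- rep("DOM", n)
  svm_left[take(rdom_a, 10L)] <- "NONDOM"  # 7 of 17 ATYP right-dominant codominant
  data.frame(id = groups$id, gmm_label = gmm, svm_left = svm_left,
             svm_right = svm_right, stringsAsFactors = FALSE)
}
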