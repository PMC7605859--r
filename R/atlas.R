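#' Homotopic-pair atlas for the sentence-processing core network
#'
#' The analysis operates on a fixed set of 18 homotopic frontal/temporal
#' region-of-interest (hROI) pairs forming the sentence-processing core
#' network (SENT_CORE), three of which -- the inferior frontal gyrus pair
#' F3t and the superior temporal sulcus pairs STS3 and STS4 -- are flagged
#' as intrinsic-connectivity hubs (SENT_HUBS). An atlas is a data frame
#' with one row per hROI (36 rows) and columns `pair_name`, `hemisphere`
#' (`"L"`/`"R"`), `volume_mm3` and `is_hub`.
#'
#' Per-hemisphere volumes may differ within a pair; network asymmetries are
#' volume-weighted means over pairs, so all volume information flows from
#' the atlas and is never hard-coded.
#'
#' @param path Path to a delimited text file (tab or comma separated) with
#'   header `pair_name, hemisphere, volume_mm3, is_hub`; `hemisphere` must
#'   be `L` or `R`, `is_hub` 0 or 1.
#' @param n_pairs Expected number of homotopic pairs (default 18).
#' @param hubs Character vector of expected hub pair names; set to `NULL`
#'   to accept whatever hub flags the file carries (any count >= 1).
#' @return A validated atlas `data.frame` of `2 * n_pairs` rows with
#'   attribute `name`.
#' @examples
#' atl <- default_atlas()
#' nrow(atl)            # 36 hROIs
#' sent_hubs(atl)       # F3t, STS3, STS4
#' @export
load_atlas <- function(path, n_pairs = 18L, hubs = c("F3t", "STS3", "STS4")) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  validate_atlas(x, n_pairs = n_pairs, hubs = hubs)
}

#' @rdname load_atlas
#' @param atlas An atlas data frame to validate.
#' @export
validate_atlas <- function(atlas, n_pairs = 18L,
                           hubs = c("F3t", "STS3", "STS4")) {
  need <- c("pair_name", "hemisphere", "volume_mm3", "is_hub")
  miss <- setdiff(need, names(atlas))
  if (length(miss)) stop("atlas is missing columns: ",
                         paste(miss, collapse = ", "))
  atlas$is_hub <- as.logical(atlas$is_hub)
  if (!all(atlas$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R' (row ",
         which(!atlas$hemisphere %in% c("L", "R"))[1L], ")")
  key <- paste(atlas$pair_name, atlas$hemisphere)
  if (anyDuplicated(key))
    stop("duplicate (pair_name, hemisphere): ", key[duplicated(key)][1L])
  bad_vol <- which(!is.finite(atlas$volume_mm3) | atlas$volume_mm3 <= 0)
  if (length(bad_vol))
    stop("non-positive volume for hROI '", atlas$pair_name[bad_vol[1L]],
         "' (", atlas$hemisphere[bad_vol[1L]], "), row ", bad_vol[1L])
  pairs <- unique(atlas$pair_name)
  if (length(pairs) != n_pairs)
    stop("expected ", n_pairs, " pairs, found ", length(pairs))
  for (p in pairs) {
    h <- sort(atlas$hemisphere[atlas$pair_name == p])
    if (!identical(h, c("L", "R")))
      stop("pair '", p, "' is missing its ",
           setdiff(c("L", "R"), h)[1L], " partner")
    hub <- unique(atlas$is_hub[atlas$pair_name == p])
    if (length(hub) != 1L)
      stop("pair '", p, "' has inconsistent is_hub flags")
  }
  hub_pairs <- sort(unique(atlas$pair_name[atlas$is_hub]))
  if (!is.null(hubs)) {
    if (!setequal(hub_pairs, hubs))
      stop("expected hub pairs {", paste(sort(hubs), collapse = ", "),
           "}, found {", paste(hub_pairs, collapse = ", "), "}")
  } else if (length(hub_pairs) < 1L) {
    stop("atlas flags no hub pairs")
  }
  # canonical ordering: pairs in first-appearance order, L block then R block
  atlas$pair_name <- factor(atlas$pair_name, levels = pairs)
  atlas <- atlas[order(atlas$hemisphere, atlas$pair_name), , drop = FALSE]
  atlas$pair_name <- as.character(atlas$pair_name)
  rownames(atlas) <- NULL
  attr(atlas, "name") <- attr(atlas, "name") %||% "SENT_CORE"
  atlas
}

#' @rdname load_atlas
#' @export
write_atlas <- function(atlas, path) {
  out <- atlas[, c("pair_name", "hemisphere", "volume_mm3", "is_hub")]
  out$is_hub <- as.integer(out$is_hub)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname load_atlas
#' @export
default_atlas <- function() {
  path <- system.file("extdata", "sensaas_synthetic_atlas.tsv",
                      package = "langlat", mustWork = TRUE)
  load_atlas(path)
}

#' @rdname load_atlas
#' @export
atlas_pairs <- function(atlas) unique(atlas$pair_name)

#' @rdname load_atlas
#' @export
sent_hubs <- function(atlas) sort(unique(atlas$pair_name[atlas$is_hub]))

#' Homotopic partner of an hROI
#'
#' Pair lookup is an involution: the partner of an hROI's partner is the
#' hROI itself.
#'
#' @param atlas An atlas data frame.
#' @param pair_name hROI pair name.
#' @param hemisphere `"L"` or `"R"`.
#' @return One-row data frame for the contralateral member of the pair.
#' @export
partner <- function(atlas, pair_name, hemisphere) {
  other <- if (hemisphere == "L") "R" else "L"
  row <- atlas[atlas$pair_name == pair_name & atlas$hemisphere == other, ]
  if (nrow(row) != 1L) stop("no partner for ", pair_name, "/", hemisphere)
  row
}

#' Pair-level volume weights
#'
#' The weight of a pair is the sum of its left and right hROI volumes,
#' symmetric under hemisphere exchange.
#'
#' @param atlas An atlas data frame.
#' @param roi_set `"SENT_CORE"` (all pairs) or `"SENT_HUBS"` (hub pairs).
#' @return Named numeric vector of weights (mm^3) in atlas pair order.
#' @export
pair_weights <- function(atlas, roi_set = c("SENT_CORE", "SENT_HUBS")) {
  roi_set <- match.arg(roi_set)
  pairs <- atlas_pairs(atlas)
  if (roi_set == "SENT_HUBS") pairs <- pairs[pairs %in% sent_hubs(atlas)]
  w <- vapply(pairs, function(p)
    sum(atlas$volume_mm3[atlas$pair_name == p]), numeric(1))
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
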