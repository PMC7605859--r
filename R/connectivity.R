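#' Least-squares linear-phase FIR bandpass design
#'
#' Designs a type-I (odd-length, symmetric) linear-phase FIR filter by
#' unweighted least squares on the amplitude response: the passband is
#' `band` (Hz), stopbands run from 0 to the lower edge minus a transition
#' and from the upper edge plus a transition to Nyquist, and transition
#' regions are don't-care. The quadratic program in the cosine-series
#' coefficients has closed-form band integrals and is solved directly.
#' Default length spans four cycles of the low cutoff (rounded to odd).
#'
#' @param band Numeric `c(low_hz, high_hz)` passband edges.
#' @param tr Sampling interval in seconds (sampling rate `1/tr`).
#' @param n_taps Filter length; default `4 / (low_hz * tr)` rounded odd.
#' @param transition Transition width in Hz (default half the low edge).
#' @return Numeric vector of filter coefficients (symmetric, odd length).
#' @export
fir_bandpass <- function(band, tr, n_taps = NULL,
                         transition = band[1L] / 2) {
  key <- paste(band[1L], band[2L], tr, n_taps %||% "auto", transition)
  cached <- .fir_cache[[key]]
  if (!is.null(cached)) return(cached)
  fs <- 1 / tr
  nyq <- fs / 2
  if (band[1L] <= 0 || band[2L] >= nyq || band[1L] >= band[2L])
    stop("band must satisfy 0 < low < high < Nyquist = ", nyq, " Hz")
  if (is.null(n_taps)) n_taps <- round(4 / (band[1L] * tr))
  n_taps <- as.integer(n_taps)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  m <- (n_taps - 1L) %/% 2L
  # normalized frequency nu in [0, 1/2]; amplitude A(nu) = a0 + 2 sum a_k cos(2 pi nu k)
  lo <- band[1L] / fs; hi <- band[2L] / fs
  tw <- transition / fs
  bands <- rbind(c(0, max(lo - tw, 0)), c(lo, hi),
                 c(min(hi + tw, 0.5), 0.5))
  des <- c(0, 1, 0)
  cosint <- function(j, f1, f2) {  # integral of cos(2 pi f j) over [f1, f2]
    if (j == 0) return(f2 - f1)
    (sin(2 * pi * f2 * j) - sin(2 * pi * f1 * j)) / (2 * pi * j)
  }
  q <- matrix(0, m + 1L, m + 1L)
  b <- numeric(m + 1L)
  for (bi in seq_len(nrow(bands))) {
    f1 <- bands[bi, 1L]; f2 <- bands[bi, 2L]
    if (f2 <= f1) next
    for (j in 0:m) {
      cj <- if (j == 0) 1 else 2
      b[j + 1L] <- b[j + 1L] + cj * des[bi] * cosint(j, f1, f2)
      for (k in j:m) {
        ck <- if (k == 0) 1 else 2
        v <- cj * ck * 0.5 * (cosint(j - k, f1, f2) + cosint(j + k, f1, f2))
        q[j + 1L, k + 1L] <- q[j + 1L, k + 1L] + v
        if (k > j) q[k + 1L, j + 1L] <- q[k + 1L, j + 1L] + v
      }
    }
  }
  a <- solve(q, b)
  # A(nu) = a0 + 2 sum_{k>=1} a_k cos(2 pi nu k); the factor 2 is folded
  # into the design matrix above, so the taps are the a_k directly
  h <- c(rev(a[-1L]), a[1L], a[-1L])
  .fir_cache[[key]] <- h
  h
}

.fir_cache <- new.env(parent = emptyenv())

#' Frequency response magnitude of a symmetric FIR filter
#'
#' @param h Symmetric odd-length coefficient vector.
#' @param freqs_hz Frequencies at which to evaluate (Hz).
#' @param tr Sampling interval (s).
#' @return Amplitude response (can be negative in stopband ripple).
#' @export
fir_response <- function(h, freqs_hz, tr) {
  m <- (length(h) - 1L) %/% 2L
  k <- -m:m
  vapply(freqs_hz, function(f)
    sum(h * cos(2 * pi * f * tr * k)), numeric(1))
}

#' Clean ROI time series: confound regression then zero-phase bandpass
#'
#' Nuisance signals (supplied confound columns, plus an intercept and a
#' linear trend, always included) are removed by ordinary least squares;
#' the residual series are then bandpass filtered with the least-squares
#' linear-phase FIR of [fir_bandpass()], applied forward and backward
#' (squared amplitude response, zero phase) with reflection padding at the
#' edges. Rank-deficient confound sets are reduced with a warning.
#'
#' @param series `n_timepoints x n_roi` matrix with attribute `tr`, or
#'   pass `tr` explicitly.
#' @param confounds Optional `n_timepoints x k` matrix of nuisance
#'   regressors.
#' @param band Passband in Hz (default 0.01-0.1).
#' @param tr Sampling interval in seconds; defaults to `attr(series, "tr")`.
#' @param n_taps Optional FIR length override.
#' @return Cleaned matrix, same shape and attributes as the input.
#' @export
clean_timeseries <- function(series, confounds = NULL, band = c(0.01, 0.1),
                             tr = attr(series, "tr"), n_taps = NULL) {
  if (is.null(tr)) stop("tr must be supplied (attribute or argument)")
  n <- nrow(series)
  x <- cbind(intercept = 1, trend = seq_len(n) - (n + 1) / 2)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n) stop("confounds must have ", n, " rows")
    x <- cbind(x, confounds)
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    warning("dropping ", ncol(x) - qx$rank, " redundant confound column(s)")
    x <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(x)
  }
  resid <- series - x %*% qr.coef(qx, series)
  h <- fir_bandpass(band, tr, n_taps = n_taps)
  g <- stats::convolve(h, rev(h), type = "open")  # forward-backward kernel
  out <- apply_symmetric_fir(resid, g)
  dimnames(out) <- dimnames(series)
  attr(out, "tr") <- tr
  out
}

# centered convolution of each column with a symmetric kernel,
# reflection-padded at the edges; FFT-based for speed
apply_symmetric_fir <- function(x, g) {
  n <- nrow(x)
  m <- (length(g) - 1L) %/% 2L
  pad <- min(m, n - 1L)
  idx_pre <- (pad + 1L):2L
  idx_post <- (n - 1L):(n - pad)
  xp <- rbind(x[idx_pre, , drop = FALSE], x, x[idx_post, , drop = FALSE])
  np <- nrow(xp)
  nfft <- stats::nextn(np + length(g) - 1L, 2L)
  gf <- stats::fft(c(g, numeric(nfft - length(g))))
  xf <- stats::mvfft(rbind(xp, matrix(0, nfft - np, ncol(x))))
  y <- Re(stats::mvfft(xf * gf, inverse = TRUE)) / nfft
  # kernel is centered at m+1; delay of full convolution is m
  y[(m + pad + 1L):(m + pad + n), , drop = FALSE]
}

#' Pearson correlation matrix of ROI time series
#'
#' @param series `n_timepoints x n_roi` matrix.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(series) {
  v <- apply(series, 2L, stats::var)
  if (any(v <= 0 | !is.finite(v)))
    stop("zero-variance column: ",
         colnames(series)[which(v <= 0 | !is.finite(v))[1L]])
  stats::cor(series)
}

#' Resting-state degree centrality of one hemisphere
#'
#' For each of the hemisphere's 18 hROIs, the degree centrality is the sum
#' of the positive correlations with the other 17 ipsilateral network
#' hROIs (negative correlations contribute zero); the hemisphere summary
#' is the mean over the 18 values and lies in `[0, 17]`. With
#' `partners = "all"` the sum instead runs over all 35 other network
#' hROIs, preserving the alternative whole-network reading.
#'
#' @param corr `36 x 36` correlation matrix with `<pair>_<hemi>` names.
#' @param atlas Atlas data frame.
#' @param hemisphere `"left"` or `"right"`.
#' @param partners `"ipsilateral"` (default) or `"all"`.
#' @return List with `per_roi` (named vector of 18) and `mean`.
#' @export
rs_dc <- function(corr, atlas, hemisphere = c("left", "right"),
                  partners = c("ipsilateral", "all")) {
  hemisphere <- match.arg(hemisphere)
  partners <- match.arg(partners)
  pairs <- atlas_pairs(atlas)
  own <- paste0(pairs, "_", if (hemisphere == "left") "L" else "R")
  cand <- if (partners == "ipsilateral") own
          else c(paste0(pairs, "_L"), paste0(pairs, "_R"))
  sub <- corr[own, cand, drop = FALSE]
  per <- vapply(seq_along(own), function(i) {
    r <- sub[i, ]
    r <- r[setdiff(names(r), own[i])]
    sum(pmax(r, 0))
  }, numeric(1))
  names(per) <- pairs
  list(per_roi = per, mean = mean(per))
}

#' Mean interhemispheric homotopic correlation
#'
#' Averages the Fisher z-transformed correlations between the 18 homotopic
#' left/right hROI pairs; reported both in z units and back-transformed to
#' the r scale.
#'
#' @inheritParams rs_dc
#' @return List with `mihhc_z` and `mihhc_r`.
#' @export
mihhc <- function(corr, atlas) {
  pairs <- atlas_pairs(atlas)
  r <- corr[cbind(paste0(pairs, "_L"), paste0(pairs, "_R"))]
  if (any(abs(r) >= 1))
    stop("homotopic correlation of +/-1 has infinite Fisher z (pair ",
         pairs[which(abs(r) >= 1)[1L]], ")")
  z <- mean(atanh(r))
  list(mihhc_z = z, mihhc_r = tanh(z))
}

#' Resting-state connectivity metrics for a cohort
#'
#' Composition of the resting-state pipeline per participant: time-series
#' cleaning (confound regression + zero-phase FIR bandpass), Pearson
#' correlation, per-hemisphere degree centrality (sum / asymmetry / mean)
#' and mean interhemispheric homotopic correlation.
#'
#' @param series_list Named list (participant id) of time-series matrices
#'   as produced by [generate_rest_timeseries()] or read from file.
#' @param atlas Atlas data frame.
#' @param band Bandpass in Hz.
#' @param confounds Optional named list of per-participant confound
#'   matrices.
#' @param dc_partners `"ipsilateral"` or `"all"`, see [rs_dc()].
#' @param clean Set `FALSE` to skip cleaning (series already filtered).
#' @return `data.frame` with `id`, `rs_dc_left`, `rs_dc_right`,
#'   `rs_dc_sum`, `rs_dc_asym`, `rs_dc_mean`, `mihhc_z`, `mihhc_r`.
#' @export
connectivity_metrics <- function(series_list, atlas, band = c(0.01, 0.1),
                                 confounds = NULL,
                                 dc_partners = c("ipsilateral", "all"),
                                 clean = TRUE) {
  dc_partners <- match.arg(dc_partners)
  ids <- names(series_list)
  rows <- lapply(ids, function(id) {
    s <- series_list[[id]]
    if (clean) s <- clean_timeseries(s, confounds = confounds[[id]],
                                     band = band)
    corr <- correlation_matrix(s)
    dl <- rs_dc(corr, atlas, "left", dc_partners)$mean
    dr <- rs_dc(corr, atlas, "right", dc_partners)$mean
    ih <- mihhc(corr, atlas)
    data.frame(id = id, rs_dc_left = dl, rs_dc_right = dr,
               rs_dc_sum = dl + dr, rs_dc_asym = dl - dr,
               rs_dc_mean = (dl + dr) / 2,
               mihhc_z = ih$mihhc_z, mihhc_r = ih$mihhc_r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
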