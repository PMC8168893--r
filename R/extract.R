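# Temporal preprocessing and extraction of the global BOLD and bottom-slice
# CSF signals. The pipeline order is fixed: spatial smoothing -> zero-phase
# band-pass -> polynomial detrend -> edge-volume discard -> mask extraction.
# Edge volumes are dropped *after* filtering so that filter edge effects are
# discarded together with the pre-steady-state volumes.

#' Discard edge volumes of a series
#'
#' Drops the first and last `n_edge` samples. With the conventional 140- or
#' 200-volume acquisitions and `n_edge = 5` this leaves 130 or 190 samples.
#'
#' @param series numeric vector.
#' @param n_edge number of samples to drop at each end (default 5).
#' @return the interior `length(series) - 2 * n_edge` samples.
#' @export
discard_edge_volumes <- function(series, n_edge = 5) {
  if (!is.numeric(n_edge) || length(n_edge) != 1L || n_edge < 0 ||
      n_edge != round(n_edge))
    stop_invalid("n_edge must be a nonnegative integer")
  n <- length(series)
  if (n <= 2 * n_edge)
    stop_invalid("series of length %d too short for n_edge = %d", n, n_edge)
  if (n_edge == 0) return(series)
  series[(n_edge + 1):(n - n_edge)]
}

#' Remove polynomial temporal trends
#'
#' Subtracts the least-squares polynomial of the given order (default
#' quadratic, i.e. linear and quadratic trend removal including the mean).
#'
#' @param series numeric vector.
#' @param order polynomial order (default 2).
#' @return detrended series, orthogonal to the fitted polynomial basis.
#' @export
detrend_poly <- function(series, order = 2) {
  n <- length(series)
  if (!is_count(order + 1)) stop_invalid("order must be a nonnegative integer")
  if (n <= order + 1)
    stop_invalid("series of length %d too short for order-%d detrending",
                 n, order)
  X <- stats::poly(seq_len(n), degree = order, raw = FALSE)
  stats::lm.fit(cbind(1, X), series)$residuals
}

# detrend every column of a T x V matrix at once
detrend_poly_matrix <- function(mat, order = 2) {
  n <- nrow(mat)
  X <- cbind(1, stats::poly(seq_len(n), degree = order, raw = FALSE))
  Q <- qr.Q(qr(X))
  mat - Q %*% crossprod(Q, mat)
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain (FFT mask) band-pass. The transfer function is real, so
#' the filter is exactly zero-phase: it cannot displace the cross-correlation
#' peaks that the coupling metric is built on. The DC component is always
#' removed. Frequency-domain filtering has wrap-around edge effects, which is
#' one reason the edge volumes are discarded after filtering.
#'
#' @param series numeric vector.
#' @param tr_seconds sampling interval in seconds.
#' @param low_hz,high_hz passband edges in Hz (defaults 0.01 and 0.1).
#' @return filtered series with exactly zero mean.
#' @export
bandpass <- function(series, tr_seconds, low_hz = 0.01, high_hz = 0.1) {
  drop(bandpass_matrix(matrix(series, ncol = 1L), tr_seconds, low_hz, high_hz))
}

bandpass_matrix <- function(mat, tr_seconds, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(is.numeric(tr_seconds), tr_seconds > 0)
  nyquist <- 1 / (2 * tr_seconds)
  if (high_hz > nyquist + 1e-12)
    stop_invalid("high cutoff %g Hz exceeds the Nyquist frequency %g Hz",
                 high_hz, nyquist)
  if (low_hz >= high_hz) stop_invalid("low_hz must be below high_hz")
  n <- nrow(mat)
  freqs <- (seq_len(n) - 1) / (n * tr_seconds)
  freqs <- pmin(freqs, 1 / tr_seconds - freqs)  # two-sided spectrum
  keep <- freqs >= low_hz & freqs <= high_hz
  keep[1L] <- FALSE                             # DC removed exactly
  ft <- stats::mvfft(mat)
  ft[!keep, ] <- 0
  Re(stats::mvfft(ft, inverse = TRUE)) / n
}

#' Per-volume spatial Gaussian smoothing
#'
#' Smooths each volume of a 4D series with a separable Gaussian kernel of
#' the given full width at half maximum, converted to voxels through the
#' stored voxel size (`sigma = FWHM / 2.3548` per axis). Kernels are
#' truncated at 3 sigma and renormalised, so an interior impulse preserves
#' its total intensity.
#'
#' @param volumes a [volume_series()].
#' @param fwhm_mm full width at half maximum in mm (default 4; 0 = identity).
#' @return a smoothed [volume_series()].
#' @export
spatial_smooth <- function(volumes, fwhm_mm = 4) {
  stopifnot(inherits(volumes, "volume_series"))
  if (fwhm_mm < 0) stop_invalid("fwhm_mm must be nonnegative")
  if (fwhm_mm == 0) return(volumes)
  if (any(!is.finite(volumes$voxel_mm)) || any(volumes$voxel_mm <= 0))
    stop_invalid("voxel size metadata missing; cannot convert FWHM to voxels")
  sigma_vox <- (fwhm_mm / 2.3548) / volumes$voxel_mm
  arr <- volumes$data
  for (axis in 1:3)
    arr <- gauss_filter_axis(arr, axis, sigma_vox[axis])
  volume_series(arr, volumes$tr_seconds, volumes$voxel_mm)
}

# 1D Gaussian convolution along one spatial axis of a 4D array
# (zero-padded; the normalised truncated kernel preserves the total
# intensity of any signal whose support stays `radius` voxels inside the
# grid, which is what the mask-based extraction relies on)
gauss_filter_axis <- function(arr, axis, sigma) {
  if (sigma <= 0) return(arr)
  radius <- max(1L, ceiling(3 * sigma))
  kern <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:4, axis))
  x <- aperm(arr, perm)                 # target axis first
  m <- matrix(x, nrow = d[axis])
  n <- d[axis]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(kern)) {
    off <- j - radius - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + kern[j] * m[src[ok], , drop = FALSE]
  }
  aperm(array(out, dim = d[perm]), order(perm))
}

# T x V matrix of masked voxel time courses
masked_matrix <- function(volumes, mask) {
  stopifnot(inherits(volumes, "volume_series"), inherits(mask, "region_mask"))
  if (!identical(dim(volumes$data)[1:3], dim(mask$data)))
    stop_invalid("mask grid %s does not match volume grid %s",
                 paste(dim(mask$data), collapse = "x"),
                 paste(dim(volumes$data)[1:3], collapse = "x"))
  idx <- which(mask$data)
  if (length(idx) == 0L) stop_invalid("empty mask")
  nt <- dim(volumes$data)[4L]
  t(matrix(volumes$data, ncol = nt)[idx, , drop = FALSE])
}

#' Extract the global BOLD signal
#'
#' Each masked voxel's time course is z-scored (sample SD) and the z-scores
#' are averaged. Because every voxel enters with unit variance, the standard
#' deviation of the average reflects inter-voxel synchrony and is at most 1;
#' it is reused downstream as the session's global-signal amplitude.
#'
#' @param volumes a [volume_series()] (already temporally preprocessed).
#' @param gm_mask gray-matter [region_mask()].
#' @return numeric vector, one value per volume.
#' @export
extract_global_signal <- function(volumes, gm_mask) {
  m <- masked_matrix(volumes, gm_mask)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(gm_mask$data)[which(sds == 0)[1L]]
    stop_invalid("masked voxel (linear index %d) has zero temporal variance",
                 bad)
  }
  rowMeans(scale(m))
}

#' Extract the bottom-slice CSF signal
#'
#' Averages the masked voxel time courses and z-scores the average once.
#' (The correlation-based coupling metric is invariant to this scaling; it
#' only fixes the presentation.) The mask is expected to sit in the lowest
#' slice along the third axis; voxels elsewhere trigger a warning but the
#' signal is still computed.
#'
#' @param volumes a [volume_series()] (already temporally preprocessed).
#' @param csf_mask bottom-slice CSF [region_mask()].
#' @return numeric vector (z-score units), one value per volume.
#' @export
extract_csf_signal <- function(volumes, csf_mask) {
  slices <- unique(which(csf_mask$data, arr.ind = TRUE)[, 3L])
  if (length(slices) && any(slices != 1L))
    warning("CSF mask extends beyond the bottom slice (slice indices ",
            paste(sort(slices), collapse = ", "), ")")
  m <- masked_matrix(volumes, csf_mask)
  zscore(rowMeans(m))
}

#' Percent-change representation of a raw-intensity series
#'
#' `100 * (x - mean(x)) / mean(x)`. Only meaningful for series with a
#' nonzero temporal mean (raw intensities, not z-scores).
#'
#' @param series numeric vector with nonzero mean.
#' @return series in percent-change units.
#' @export
percent_change <- function(series) {
  m <- mean(series)
  if (!is.finite(m) || abs(m) < 1e-12 * max(1, stats::sd(series)))
    stop_invalid("percent_change needs a series with nonzero temporal mean")
  100 * (series - m) / m
}

#' Negative temporal derivative
#'
#' Forward difference `-(x[t+1] - x[t]) / tr`, assigned to the leading
#' timepoint `t`; the result has length `T - 1`. The stencil convention
#' matters: a +/-1 sample shift would move the derivative cross-correlation
#' peak by one TR.
#'
#' @param series numeric vector of length >= 2.
#' @param tr_seconds sampling interval in seconds.
#' @return numeric vector of length `length(series) - 1`.
#' @export
negative_derivative <- function(series, tr_seconds) {
  if (length(series) < 2L) stop_invalid("need at least 2 samples")
  stopifnot(tr_seconds > 0)
  -diff(series) / tr_seconds
}

#' Run the full temporal pipeline and extract session signals
#'
#' Applies, in this order: spatial smoothing, zero-phase band-pass,
#' polynomial detrending (all voxelwise), edge-volume discard, then
#' extraction of the global BOLD signal ([extract_global_signal()]) and the
#' bottom-slice CSF signal ([extract_csf_signal()]).
#'
#' @param volumes a [volume_series()].
#' @param gm_mask,csf_mask region masks, see [region_mask()].
#' @param fwhm_mm spatial smoothing FWHM in mm (default 4).
#' @param low_hz,high_hz band-pass edges (defaults 0.01, 0.1 Hz).
#' @param detrend_order polynomial detrending order (default 2).
#' @param n_edge edge volumes discarded at each end (default 5).
#' @return a `session_signals` object: `global_bold`, `csf`, `tr_seconds`,
#'   `n_discarded_edge_volumes`, and a `provenance` list of applied steps.
#' @export
extract_session_signals <- function(volumes, gm_mask, csf_mask,
                                    fwhm_mm = 4, low_hz = 0.01, high_hz = 0.1,
                                    detrend_order = 2, n_edge = 5) {
  stopifnot(inherits(volumes, "volume_series"))
  sm <- spatial_smooth(volumes, fwhm_mm)
  d <- dim(sm$data)
  mat <- t(matrix(sm$data, ncol = d[4L]))          # T x V
  mat <- bandpass_matrix(mat, sm$tr_seconds, low_hz, high_hz)
  mat <- detrend_poly_matrix(mat, detrend_order)
  keep <- (n_edge + 1):(d[4L] - n_edge)
  if (length(keep) < 2L) stop_invalid("too few volumes after edge discard")
  mat <- mat[keep, , drop = FALSE]
  arr <- array(t(mat), dim = c(d[1:3], length(keep)))
  filt <- volume_series(arr, sm$tr_seconds, sm$voxel_mm)
  session_signals(
    global_bold = extract_global_signal(filt, gm_mask),
    csf = extract_csf_signal(filt, csf_mask),
    tr_seconds = sm$tr_seconds,
    n_discarded_edge_volumes = n_edge,
    provenance = list(spatial_smooth_fwhm_mm = fwhm_mm,
                      bandpass_hz = c(low_hz, high_hz),
                      detrend_order = detrend_order,
                      edge_discard = n_edge,
                      order = c("smooth", "bandpass", "detrend",
                                "edge-discard", "extract")))
}

#' Session signal pair container
#'
#' @param global_bold global BOLD series (average of voxelwise z-scores).
#' @param csf CSF series (z-score units).
#' @param tr_seconds repetition time.
#' @param n_discarded_edge_volumes edge volumes dropped at each end.
#' @param provenance list describing the preprocessing applied.
#' @return an object of class `session_signals`.
#' @export
session_signals <- function(global_bold, csf, tr_seconds,
                            n_discarded_edge_volumes = 0,
                            provenance = list()) {
  if (length(global_bold) != length(csf))
    stop_invalid("global and CSF series differ in length (%d vs %d)",
                 length(global_bold), length(csf))
  structure(list(global_bold = as.numeric(global_bold),
                 csf = as.numeric(csf),
                 tr_seconds = tr_seconds,
                 n_discarded_edge_volumes = n_discarded_edge_volumes,
                 provenance = provenance),
            class = "session_signals")
}

#' @export
print.session_signals <- function(x, ...) {
  cat(sprintf("<session_signals> %d samples at TR = %g s (%d edge volumes discarded per end)\n",
              length(x$global_bold), x$tr_seconds,
              x$n_discarded_edge_volumes))
  invisible(x)
}

#' Temporal pipeline for an already-extracted signal pair
#'
#' The signal-only fast path of the synthetic generator skips volume
#' assembly; this helper applies the same temporal steps (band-pass,
#' detrend, edge discard, normalisation) to a raw global/CSF signal pair so
#' that both generator modes feed identical downstream analyses.
#'
#' @param g_raw,f_raw raw global and CSF series at TR resolution.
#' @param tr_seconds repetition time.
#' @inheritParams extract_session_signals
#' @return a [session_signals()] object.
#' @export
process_signal_pair <- function(g_raw, f_raw, tr_seconds,
                                low_hz = 0.01, high_hz = 0.1,
                                detrend_order = 2, n_edge = 5) {
  pipe <- function(x) {
    x <- bandpass(x, tr_seconds, low_hz, high_hz)
    x <- detrend_poly(x, detrend_order)
    discard_edge_volumes(x, n_edge)
  }
  session_signals(
    global_bold = zscore(pipe(g_raw)),
    csf = zscore(pipe(f_raw)),
    tr_seconds = tr_seconds,
    n_discarded_edge_volumes = n_edge,
    provenance = list(bandpass_hz = c(low_hz, high_hz),
                      detrend_order = detrend_order,
                      edge_discard = n_edge,
                      order = c("bandpass", "detrend", "edge-discard",
                                "normalise")))
}
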