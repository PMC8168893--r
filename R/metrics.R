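# Session-level state and nuisance metrics: global-signal amplitude,
# template-based arousal index, framewise displacement.

#' Global-signal fluctuation amplitude
#'
#' The sample standard deviation of the global BOLD signal. Because the
#' global signal is an average of per-voxel z-scores, its SD indexes global
#' synchrony and tracks the arousal state (larger in drowsiness/sleep).
#'
#' @param global_signal numeric series (length >= 2).
#' @return scalar SD.
#' @export
global_amplitude <- function(global_signal) {
  if (length(global_signal) < 2L) stop_invalid("need at least 2 samples")
  stats::sd(global_signal)
}

#' Template-based arousal index
#'
#' Correlates every volume spatially with an arousal template over the
#' template's support and takes the sample SD of the resulting time course.
#' Invariant to affine rescaling of the template.
#'
#' @param volumes a [volume_series()] (>= 2 volumes).
#' @param template 3D numeric array (or [region_mask()]-aligned value map)
#'   on the volume grid; voxels with nonzero template value form the
#'   support. Must be nonconstant over its support.
#' @return scalar arousal index.
#' @export
arousal_index <- function(volumes, template) {
  stopifnot(inherits(volumes, "volume_series"))
  if (inherits(template, "region_mask")) template <- template$data * 1
  if (!is.array(template) || !identical(dim(template), dim(volumes$data)[1:3]))
    stop_invalid("template grid does not match the volume grid")
  idx <- which(template != 0)
  if (length(idx) < 2L) stop_invalid("template support has fewer than 2 voxels")
  tv <- as.numeric(template)[idx]
  if (stats::sd(tv) == 0)
    stop_invalid("template is constant over its support")
  nt <- dim(volumes$data)[4L]
  if (nt < 2L) stop_invalid("need at least 2 volumes")
  vm <- matrix(volumes$data, ncol = nt)[idx, , drop = FALSE]
  cors <- suppressWarnings(stats::cor(vm, tv))
  stats::sd(drop(cors))
}

#' Framewise displacement from realignment parameters
#'
#' `FD_t = sum(|delta translation|) + radius * sum(|delta rotation|)`,
#' with backward differences over consecutive frames (T-1 values) and
#' rotations (radians) converted to arc length on a sphere of the given
#' radius. The session's head-motion level is the mean over the T-1 values.
#'
#' @param motion_params numeric T x 6 matrix (or 6 x T): three translations
#'   in mm then three rotations in radians, one row per volume.
#' @param radius_mm sphere radius for the rotation arc length (default 50).
#' @return list with `fd` (length T-1) and `mean_fd`.
#' @export
framewise_displacement <- function(motion_params, radius_mm = 50) {
  mp <- as.matrix(motion_params)
  if (ncol(mp) != 6L && nrow(mp) == 6L) mp <- t(mp)
  if (ncol(mp) != 6L)
    stop_invalid("motion_params must have 6 parameter series, got %d",
                 ncol(mp))
  if (nrow(mp) < 2L) stop_invalid("need at least 2 frames")
  d <- abs(diff(mp))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    radius_mm * rowSums(d[, 4:6, drop = FALSE])
  list(fd = unname(fd), mean_fd = mean(fd))
}

#' Compute session metrics for a cohort
#'
#' Convenience wrapper collecting [global_amplitude()], [arousal_index()]
#' (volume mode only) and [framewise_displacement()] per session.
#'
#' @param signals list of [session_signals()].
#' @param motion list of per-session motion-parameter matrices (or `NULL`).
#' @param volumes list of per-session [volume_series()] (or `NULL`).
#' @param template arousal template for [arousal_index()] (or `NULL`).
#' @return data.frame with one row per session: `amplitude`,
#'   `arousal_index`, `mean_fd` (NA where inputs are unavailable).
#' @export
session_metrics <- function(signals, motion = NULL, volumes = NULL,
                            template = NULL) {
  n <- length(signals)
  amp <- vapply(signals, function(s) global_amplitude(s$global_bold), 1)
  fd <- rep(NA_real_, n)
  if (!is.null(motion))
    fd <- vapply(motion, function(m) framewise_displacement(m)$mean_fd, 1)
  ai <- rep(NA_real_, n)
  if (!is.null(volumes) && !is.null(template))
    ai <- vapply(volumes, arousal_index, 1, template = template)
  data.frame(amplitude = amp, arousal_index = ai, mean_fd = fd)
}
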