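#' 4D volume series container
#'
#' A light container for a 4D intensity array in `(x, y, z, t)` order with
#' its repetition time and voxel size. The third array axis is the slice
#' axis; slice index 1 is the bottom of the imaging volume, where the CSF
#' inflow effect is measured.
#'
#' @param data numeric 4D array `(x, y, z, t)`.
#' @param tr_seconds repetition time in seconds (> 0).
#' @param voxel_mm length-3 voxel size in mm.
#' @return an object of class `volume_series`.
#' @export
volume_series <- function(data, tr_seconds, voxel_mm = c(3, 3, 3)) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop_invalid("volume_series needs a 4D array, got %dD",
                 length(dim(data) %||% length(data)))
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop_invalid("tr_seconds must be a positive scalar")
  stopifnot(length(voxel_mm) == 3L, all(voxel_mm > 0))
  structure(list(data = data, tr_seconds = as.numeric(tr_seconds),
                 voxel_mm = as.numeric(voxel_mm)),
            class = "volume_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %d x %d x %d voxels, %d volumes, TR = %g s, voxel %g x %g x %g mm\n",
              d[1], d[2], d[3], d[4], x$tr_seconds,
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3]))
  invisible(x)
}

#' 3D region mask container
#'
#' @param data logical (or 0/1 numeric) 3D array aligned to a
#'   [volume_series()] grid.
#' @param role what the mask selects: gray matter, bottom-slice CSF, or an
#'   arbitrary template support.
#' @return an object of class `region_mask`.
#' @export
region_mask <- function(data, role = c("gray-matter", "csf-bottom-slice",
                                       "template")) {
  role <- match.arg(role)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_invalid("region_mask needs a 3D array")
  data <- array(as.logical(data), dim = dim(data))
  if (anyNA(data)) stop_invalid("mask contains NA")
  structure(list(data = data, role = role), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> role = %s, %d voxels in a %s grid\n",
              x$role, sum(x$data), paste(dim(x$data), collapse = " x ")))
  invisible(x)
}

#' Read a 4D NIfTI series as a volume_series
#'
#' The repetition time is taken from the time pixel-dimension of the header
#' unless `tr_seconds` is given, in which case the header value is overridden
#' with a warning.
#'
#' @param path NIfTI-1 file with 4D data.
#' @param tr_seconds optional TR override in seconds.
#' @return a [volume_series()].
#' @export
read_volume <- function(path, tr_seconds = NULL) {
  nii <- read_nifti(path)
  if (length(nii$dim) != 4L)
    stop_invalid("%s is %dD; a 4D series was expected", path, length(nii$dim))
  hdr_tr <- unname(nii$pixdim["dt"])
  if (!is.null(tr_seconds)) {
    if (is.finite(hdr_tr) && hdr_tr > 0 && abs(hdr_tr - tr_seconds) > 1e-6)
      warning(sprintf("TR override: header says %g s, using %g s",
                      hdr_tr, tr_seconds))
    tr <- tr_seconds
  } else {
    if (!is.finite(hdr_tr) || hdr_tr <= 0)
      stop_invalid("%s has no usable TR in its header; pass tr_seconds", path)
    tr <- hdr_tr
  }
  voxel <- unname(nii$pixdim[c("dx", "dy", "dz")])
  if (any(!is.finite(voxel)) || any(voxel <= 0)) voxel <- c(3, 3, 3)
  volume_series(nii$data, tr_seconds = tr, voxel_mm = voxel)
}

#' Read a 3D NIfTI mask as a region_mask
#'
#' Nonzero voxels are in-mask.
#'
#' @param path NIfTI-1 file with 3D data.
#' @param role mask role, see [region_mask()].
#' @return a [region_mask()].
#' @export
read_mask <- function(path, role = "gray-matter") {
  nii <- read_nifti(path)
  if (length(nii$dim) != 3L)
    stop_invalid("%s is %dD; a 3D mask was expected", path, length(nii$dim))
  region_mask(nii$data != 0, role = role)
}
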