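# Minimal NIfTI-1 I/O.
#
# No NIfTI package is available in this toolchain, so the single-file format
# (.nii, optionally gzipped) is handled directly. Only the fields this
# package interprets are exposed: dim, pixdim (voxel size in mm and TR in
# seconds), datatype, and the scl_slope/scl_inter intensity scaling.
# Supported on read: uint8, int16, int32, float32, float64, little or big
# endian. Written files are little-endian float32 by default.

NIFTI_HDR_SIZE <- 348L

.nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE)
)

#' Read a NIfTI-1 image
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into an array plus
#' the pixel-dimension metadata. Intensity scaling (`scl_slope`/`scl_inter`)
#' is applied when present.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a list with elements `data` (numeric array), `dim`, `pixdim`
#'   (named: `dx`, `dy`, `dz` in mm; `dt` in seconds for 4D images).
#' @seealso [write_nifti()], [read_volume()], [read_mask()]
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", NIFTI_HDR_SIZE)
  if (length(hdr_raw) < NIFTI_HDR_SIZE)
    stop_invalid("not a NIfTI-1 file (truncated header): %s", path)
  rd <- function(offset, what, n, size, endian) {
    readBin(hdr_raw[(offset + 1L):length(hdr_raw)], what, n = n, size = size,
            endian = endian, signed = TRUE)
  }
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L, "little") != NIFTI_HDR_SIZE) {
    endian <- "big"
    if (rd(0L, "integer", 1L, 4L, "big") != NIFTI_HDR_SIZE)
      stop_invalid("not a NIfTI-1 file (bad sizeof_hdr): %s", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop_invalid("not a NIfTI-1 file (bad magic '%s'): %s", magic, path)
  if (magic == "ni1")
    stop_invalid("two-file (.hdr/.img) NIfTI is not supported: %s", path)
  dim0 <- rd(40L, "integer", 8L, 2L, endian)
  ndim <- dim0[1L]
  if (ndim < 1L || ndim > 7L)
    stop_invalid("bad ndim %d in %s", ndim, path)
  dims <- dim0[2L:(1L + ndim)]
  datatype <- rd(70L, "integer", 1L, 2L, endian)
  spec <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(spec))
    stop_invalid("unsupported NIfTI datatype code %d in %s", datatype, path)
  pixdim <- rd(76L, "double", 8L, 4L, endian)
  vox_offset <- rd(108L, "double", 1L, 4L, endian)
  scl_slope <- rd(112L, "double", 1L, 4L, endian)
  scl_inter <- rd(116L, "double", 1L, 4L, endian)
  skip <- as.integer(round(vox_offset)) - NIFTI_HDR_SIZE
  if (skip > 0L) readBin(con, "raw", skip)
  n_vox <- prod(dims)
  data <- readBin(con, spec$what, n = n_vox, size = spec$size,
                  endian = endian, signed = spec$signed)
  if (length(data) != n_vox)
    stop_invalid("truncated NIfTI data in %s (expected %d values, got %d)",
                 path, n_vox, length(data))
  data <- as.double(data)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  arr <- array(data, dim = dims)
  pd <- pixdim[2L:(1L + ndim)]
  names(pd) <- c("dx", "dy", "dz", "dt", "d5", "d6", "d7")[seq_len(ndim)]
  list(data = arr, dim = dims, pixdim = pd)
}

#' Write a NIfTI-1 image
#'
#' Writes an array as a single-file little-endian NIfTI-1 image. 3D and 4D
#' arrays are supported; for 4D arrays `tr_seconds` is stored in the fourth
#' pixel dimension.
#'
#' @param data numeric or logical array (3D or 4D).
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param voxel_mm length-3 voxel size in mm.
#' @param tr_seconds repetition time stored in pixdim\\[4\\] (4D only).
#' @param datatype `"float32"` (default), `"float64"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_mm = c(3, 3, 3), tr_seconds = NULL,
                        datatype = c("float32", "float64", "uint8")) {
  datatype <- match.arg(datatype)
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  nd <- length(dim(data))
  if (nd < 3L || nd > 4L) stop_invalid("only 3D or 4D arrays are written")
  stopifnot(length(voxel_mm) == 3L, all(voxel_mm > 0))
  dt_code <- switch(datatype, float32 = 16L, float64 = 64L, uint8 = 2L)
  bitpix <- switch(datatype, float32 = 32L, float64 = 64L, uint8 = 8L)
  dim8 <- integer(8L)
  dim8[1L] <- nd
  dim8[2L:(1L + nd)] <- dim(data)
  dim8[dim8 == 0L] <- 1L
  pixdim8 <- numeric(8L)
  pixdim8[1L] <- 1
  pixdim8[2L:4L] <- voxel_mm
  if (nd == 4L) pixdim8[5L] <- if (is.null(tr_seconds)) 0 else tr_seconds

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(NIFTI_HDR_SIZE, 4L)                       # sizeof_hdr
  w(raw(36L), 1L)                             # data_type..dim_info (unused)
  w(as.integer(dim8), 2L)                     # dim
  w(numeric(3L), 4L)                          # intent_p1..p3
  w(0L, 2L)                                   # intent_code
  w(dt_code, 2L)                              # datatype
  w(bitpix, 2L)                               # bitpix
  w(0L, 2L)                                   # slice_start
  w(pixdim8, 4L)                              # pixdim
  w(352, 4L)                                  # vox_offset
  w(1, 4L)                                    # scl_slope
  w(0, 4L)                                    # scl_inter
  w(0L, 2L)                                   # slice_end
  w(raw(1L), 1L)                              # slice_code
  w(as.raw(bitwOr(2L, 8L)), 1L)               # xyzt_units: mm | sec
  w(numeric(4L), 4L)                          # cal_max..toffset
  w(integer(2L), 4L)                          # glmax, glmin
  w(raw(104L), 1L)                            # descrip, aux_file
  w(c(0L, 1L), 2L)                            # qform_code, sform_code = 1
  w(numeric(6L), 4L)                          # quatern, qoffset
  srow <- rbind(c(voxel_mm[1L], 0, 0, 0),
                c(0, voxel_mm[2L], 0, 0),
                c(0, 0, voxel_mm[3L], 0))
  w(as.numeric(t(srow)), 4L)                  # srow_x/y/z
  w(raw(16L), 1L)                             # intent_name
  w(c(charToRaw("n+1"), as.raw(0L)), 1L)      # magic
  w(raw(4L), 1L)                              # header extension flag
  vals <- as.numeric(data)
  if (datatype == "uint8") w(as.integer(vals), 1L) else w(vals, bitpix %/% 8L)
  invisible(path)
}
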