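# Minimal NIfTI-1 I/O (single-file .nii / .nii.gz, 3D volumes).
#
# No NIfTI-capable package is available in the supported dependency set, so
# the small subset of the format needed here -- a 348-byte NIfTI-1 header,
# little-endian, sform-only affine, common datatypes -- is implemented
# directly. Round-trips were cross-validated against nibabel.

NIFTI_DT <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                 `4` = list(what = "integer", size = 2, signed = TRUE),
                 `8` = list(what = "integer", size = 4, signed = TRUE),
                 `16` = list(what = "numeric", size = 4, signed = TRUE),
                 `64` = list(what = "numeric", size = 8, signed = TRUE))

nii_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`), returning a
#' [volume_map()]. Supports uint8, int16, int32, float32 and float64 data,
#' either endianness, and applies `scl_slope`/`scl_inter` when set. Only the
#' first 3 dimensions are read (one volume).
#'
#' @param path file path.
#' @param units unit label to attach to the result.
#' @return a [volume_map()].
#' @export
read_nifti <- function(path, units = "") {
  con <- nii_connection(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- if (sz == 348L) "little" else "big"
  readBin(con, "raw", 36)                       # data_type..regular + dim_info
  dims <- readBin(con, "integer", 8, size = 2, endian = endian)
  ndim <- dims[1]
  if (ndim < 3L) stop("need a 3D NIfTI volume: ", path)
  dm <- dims[2:4]
  readBin(con, "numeric", 3, size = 4, endian = endian)  # intent_p1..p3
  readBin(con, "integer", 1, size = 2, endian = endian)  # intent_code
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "integer", 2, size = 2, endian = endian)  # bitpix, slice_start
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  # skip the rest of the header up to the data offset
  readBin(con, "raw", as.integer(vox_offset) - 120L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  n <- prod(dm)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  volume_map(array(vals, dm), voxel_size_mm = abs(pixdim[2:4]), units = units)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D array or [volume_map()] as a little-endian single-file NIfTI-1
#' image (float64, or uint8 for logical masks), with an sform affine encoding
#' the voxel spacing. Compression is chosen from the file extension.
#'
#' @param x [volume_map()], 3D numeric array, or logical mask array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size_mm spacing, used when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, voxel_size_mm = c(1, 1, 1)) {
  if (inherits(x, "volume_map")) {
    voxel_size_mm <- x$voxel_size_mm
    x <- x$values
  }
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (!is.array(x) || length(dim(x)) != 3L) stop("'x' must be a 3D array")
  dm <- dim(x)
  logical_in <- is.logical(x) ||
    (is.integer(x) && all(x %in% c(0L, 1L)))
  datatype <- if (logical_in) 2L else 64L
  bitpix <- if (logical_in) 8L else 64L
  con <- nii_connection(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  wn <- function(v) writeBin(as.double(v), con, size = 4, endian = "little")
  wc <- function(s, len) {
    r <- charToRaw(s)
    writeBin(c(r, raw(len - length(r))), con)
  }
  wi(348, 4)                               # sizeof_hdr
  writeBin(raw(35), con)                   # data_type, db_name, extents, ...
  writeBin(raw(1), con)                    # dim_info
  wi(c(3, dm, 1, 1, 1, 1), 2)              # dim[8]
  wn(c(0, 0, 0))                           # intent_p1..p3
  wi(0, 2)                                 # intent_code
  wi(datatype, 2)
  wi(bitpix, 2)
  wi(0, 2)                                 # slice_start
  wn(c(1, voxel_size_mm, 0, 0, 0, 0))      # pixdim[8] (qfac 1)
  wn(352)                                  # vox_offset
  wn(c(1, 0))                              # scl_slope, scl_inter
  wi(0, 2)                                 # slice_end
  writeBin(raw(2), con)                    # slice_code, xyzt_units
  wn(c(0, 0, 0, 0))                        # cal_max, cal_min, slice_dur, toffset
  wi(c(0, 0), 4)                           # glmax, glmin
  wc("penumbra", 80)                       # descrip
  wc("", 24)                               # aux_file
  wi(c(0, 1), 2)                           # qform_code, sform_code
  wn(c(0, 0, 0, 0, 0, 0))                  # quatern b,c,d + qoffset x,y,z
  wn(c(voxel_size_mm[1], 0, 0, 0))         # srow_x
  wn(c(0, voxel_size_mm[2], 0, 0))         # srow_y
  wn(c(0, 0, voxel_size_mm[3], 0))         # srow_z
  wc("", 16)                               # intent_name
  wc("n+1", 4)                             # magic
  writeBin(raw(4), con)                    # no extensions
  if (logical_in) {
    writeBin(as.integer(x), con, size = 1, endian = "little")
  } else {
    writeBin(as.double(x), con, size = 8, endian = "little")
  }
  invisible(path)
}
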