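#' Construct a volume map
#'
#' A `volume_map` is one 3D scalar metric (or probability) field on a voxel
#' grid with physical spacing. It is the container used for metric maps
#' (chi-negative and chi-positive in ppm, MD/RD in mm^2/s, free water
#' unitless), probability maps and frequency maps.
#'
#' @param values 3D numeric array.
#' @param voxel_size_mm positive per-axis spacing in mm; a scalar is recycled
#'   to the three axes.
#' @param units free-text unit label (e.g. `"ppm"`, `"mm^2/s"`, `"percent"`).
#' @return object of class `volume_map` with fields `values`, `voxel_size_mm`,
#'   `units`.
#' @examples
#' vm <- volume_map(array(0, c(4, 4, 4)), voxel_size_mm = 2, units = "ppm")
#' dim(vm$values)
#' @export
volume_map <- function(values, voxel_size_mm = c(1, 1, 1), units = "") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be 3 positive finite values")
  structure(list(values = values, voxel_size_mm = voxel_size_mm,
                 units = units),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  cat(sprintf("<volume_map> %s voxels @ %s mm%s\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x"),
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

# Coerce a volume_map or 3D array to a plain 3D array.
as_vol_array <- function(x, what = "volume") {
  if (inherits(x, "volume_map")) x <- x$values
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("'%s' must be a 3D array or volume_map", what))
  x
}

# Coerce to logical 3D array (binary mask).
as_mask_array <- function(x, what = "mask") {
  x <- as_vol_array(x, what)
  if (!is.logical(x)) {
    if (any(!(x %in% c(0, 1)) & is.finite(x)))
      stop(sprintf("'%s' is not binary", what))
    x <- array(x != 0, dim(x))
  }
  x
}

check_same_grid <- function(a, b, name_a = "first", name_b = "second") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("grid mismatch: %s is %s but %s is %s",
                 name_a, paste(dim(a), collapse = "x"),
                 name_b, paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

#' Euclidean distance to a mask
#'
#' Exact Euclidean distance transform (voxel-centre to voxel-centre) with
#' per-axis physical spacing: each voxel receives the distance in mm to the
#' nearest voxel of `mask` (0 inside the mask, `Inf` if the mask is empty).
#'
#' @param mask logical 3D array (or `volume_map` of 0/1).
#' @param voxel_size_mm per-axis spacing in mm.
#' @return numeric 3D array of distances in mm.
#' @export
distance_to_mask <- function(mask, voxel_size_mm = c(1, 1, 1)) {
  m <- as_mask_array(mask)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  array(.edt_cpp(as.logical(m), dim(m), voxel_size_mm), dim(m))
}

#' Morphological erosion/dilation by a physical ball
#'
#' Erosion keeps a voxel iff the closed ball of radius `radius_mm` around it
#' lies entirely inside the mask, i.e. iff its distance to the background
#' exceeds `radius_mm`. Dilation adds every voxel within `radius_mm` of the
#' mask. Radii are in mm and converted per-axis through the spacing, so the
#' structuring element is a true physical ball on anisotropic grids.
#'
#' @param mask logical 3D array.
#' @param radius_mm ball radius in mm.
#' @param voxel_size_mm per-axis spacing in mm.
#' @return logical 3D array.
#' @export
ball_erode <- function(mask, radius_mm, voxel_size_mm = c(1, 1, 1)) {
  m <- as_mask_array(mask)
  if (radius_mm < 0) stop("'radius_mm' must be >= 0")
  if (radius_mm == 0 || !any(m)) return(m)
  d_bg <- distance_to_mask(!m, voxel_size_mm)
  m & (d_bg > radius_mm)
}

#' @rdname ball_erode
#' @export
ball_dilate <- function(mask, radius_mm, voxel_size_mm = c(1, 1, 1)) {
  m <- as_mask_array(mask)
  if (radius_mm < 0) stop("'radius_mm' must be >= 0")
  if (radius_mm == 0 || !any(m)) return(m)
  distance_to_mask(m, voxel_size_mm) <= radius_mm
}

#' Connected components of a binary volume
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return integer 3D array of component labels, 0 outside the mask.
#' @export
label_components <- function(mask, connectivity = 26) {
  m <- as_mask_array(mask)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  array(.label_components_cpp(as.logical(m), dim(m), connectivity), dim(m))
}

# FFT of a wrapped (circular) Gaussian kernel; reusable across many
# smoothing calls on the same grid.
gauss_kernel_fft <- function(dm, sigma_mm, voxel_size_mm) {
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  kern1 <- function(n, sp) {
    pos <- (seq_len(n) - 1)
    d <- pmin(pos, n - pos) * sp
    k <- exp(-0.5 * (d / sigma_mm)^2)
    k / sum(k)
  }
  kern <- outer(outer(kern1(dm[1], voxel_size_mm[1]),
                      kern1(dm[2], voxel_size_mm[2])),
                kern1(dm[3], voxel_size_mm[3]))
  dim(kern) <- dm
  fft(kern)
}

# Gaussian smoothing of a 3D field via FFT (circular boundary); used by the
# cohort simulator to grow confluent lesion shapes.
gaussian_smooth_3d <- function(x, sigma_mm, voxel_size_mm = c(1, 1, 1),
                               kern_fft = NULL) {
  x <- as_vol_array(x)
  dm <- dim(x)
  if (is.null(kern_fft))
    kern_fft <- gauss_kernel_fft(dm, sigma_mm, voxel_size_mm)
  out <- Re(fft(fft(x) * kern_fft, inverse = TRUE)) / prod(dm)
  array(out, dm)
}
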