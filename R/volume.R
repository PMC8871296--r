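#' CT image volume
#'
#' Container for a 3D grid of Hounsfield-unit (HU) voxels with physical
#' spacing. Voxels are stored in the R/NIfTI-native axis order
#' `voxels[ix, iy, iz]` with `dim = c(nx, ny, nz)`; the third axis is the
#' slice (z) axis. `spacing` and `origin` follow the same (x, y, z) order
#' and are in millimetres.
#'
#' @param voxels 3D numeric array of HU values; all values must be finite.
#' @param spacing numeric length-3, voxel pitch (dx, dy, dz) in mm, all > 0.
#' @param origin numeric length-3, physical position of voxel (1,1,1) in mm.
#' @return An object of class `image_volume` with elements `voxels`,
#'   `spacing`, `origin`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (!all(is.finite(voxels)))
    stop("all voxel values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (dx, dy, dz) in mm")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

is_image_volume <- function(x) inherits(x, "image_volume")

stopifnot_volume <- function(x) {
  if (!is_image_volume(x)) stop("expected an `image_volume`")
  invisible(x)
}

#' Read a NIfTI-1 volume
#'
#' Loads a `.nii`/`.nii.gz` file into an [image_volume], taking the voxel
#' spacing from the header `pixdim`.
#'
#' @param path file path.
#' @return An [image_volume].
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- as.array(img)
  if (length(dim(vox)) != 3L) stop("expected a 3D NIfTI volume")
  sp <- RNifti::pixdim(img)[1:3]
  image_volume(vox, spacing = sp)
}

#' Write a volume (or mask) as NIfTI-1
#'
#' @param volume an [image_volume], or a 3D logical/integer array (written
#'   as uint8, e.g. a segmentation mask) together with `spacing`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param spacing required when `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(volume, path, spacing = NULL) {
  if (is_image_volume(volume)) {
    arr <- volume$voxels
    sp <- volume$spacing
    dt <- "double"
  } else {
    if (is.null(spacing)) stop("`spacing` is required for a bare array")
    arr <- array(as.integer(volume), dim = dim(volume))
    sp <- spacing
    dt <- "uint8"
  }
  attr(arr, "pixdim") <- sp
  img <- RNifti::asNifti(arr, datatype = dt)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' In-plane Gaussian blur
#'
#' Blurs every slice of a volume with an isotropic 2D Gaussian point spread
#' function of standard deviation `sigma_mm`, applied exactly in the
#' frequency domain (transfer function `exp(-2 pi^2 sigma^2 f^2)`).
#' `sigma_mm = 0` returns the input unchanged. Boundaries are periodic;
#' keep objects away from the volume edge.
#'
#' @param volume an [image_volume].
#' @param sigma_mm PSF standard deviation in mm, >= 0.
#' @return A blurred [image_volume].
#' @export
blur_inplane <- function(volume, sigma_mm) {
  stopifnot_volume(volume)
  if (sigma_mm < 0) stop("`sigma_mm` must be >= 0")
  if (sigma_mm == 0) return(volume)
  d <- dim(volume$voxels)
  fx <- fft_freq(d[1], volume$spacing[1])
  fy <- fft_freq(d[2], volume$spacing[2])
  f2 <- outer(fx^2, fy^2, "+")
  h <- exp(-2 * pi^2 * sigma_mm^2 * f2)
  out <- volume$voxels
  for (k in seq_len(d[3])) {
    out[, , k] <- Re(stats::fft(stats::fft(volume$voxels[, , k]) * h,
                                inverse = TRUE)) / (d[1] * d[2])
  }
  image_volume(out, volume$spacing, volume$origin)
}

# DFT sample frequencies (cycles/mm), unshifted order as returned by fft().
fft_freq <- function(n, d) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

# Physical (x, y) coordinate grids of in-plane voxel centres, relative to
# the slice centre, in mm.
plane_coords <- function(nx, ny, spacing) {
  x <- (seq_len(nx) - (nx + 1) / 2) * spacing[1]
  y <- (seq_len(ny) - (ny + 1) / 2) * spacing[2]
  list(x = matrix(x, nx, ny), y = matrix(y, nx, ny, byrow = TRUE))
}
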