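# Shared synthetic fixtures. Geometry mirrors the study conditions the
# package emulates: an ultra-high-resolution insert grid for TTF, a
# reconstruction-matrix water stack for NPS, and a chest at lung HU.

ttf_phantom <- function(psf_sigma_mm = 0.5, n_slices = 2, pixel_mm = 0.2,
                        noise = NULL) {
  make_cylinder_phantom(phantom_spec(phantom_diameter_mm = 72,
                                     insert_diameter_mm = 50),
                        shape = c(384, 384, n_slices),
                        spacing = c(pixel_mm, pixel_mm, 1.5),
                        psf_sigma_mm = psf_sigma_mm, noise = noise)
}

white_stack <- function(sigma_hu, seed, n_px = 128, n_slices = 50,
                        pixel_mm = 0.586) {
  make_noise_field(c(n_px, n_px, n_slices),
                   c(pixel_mm, pixel_mm, 1.5),
                   noise_model("white", sigma_hu, seed = seed))
}

small_chest <- function(sigma_hu = 0, seed = 1, n_vessels = 3,
                        shape = c(192, 192, 32),
                        spacing = c(1.8, 1.8, 2.5), psf_sigma_mm = 0.6) {
  noise <- if (sigma_hu > 0) noise_model("white", sigma_hu, seed = seed)
  make_chest_phantom(chest_spec(body_semiaxes_mm = c(150, 95),
                                lung_semiaxes_mm = c(50, 60, 32),
                                n_vessels = n_vessels),
                     shape = shape, spacing = spacing,
                     psf_sigma_mm = psf_sigma_mm, noise = noise)
}

gaussian_mtf <- function(f, sigma_mm) exp(-2 * pi^2 * sigma_mm^2 * f^2)

# analytic Gaussian-MTF landmark: frequency where the MTF falls to `frac`
gaussian_mtf_landmark <- function(sigma_mm, frac) {
  sqrt(log(1 / frac) / (2 * pi^2)) / sigma_mm
}

rotate90_volume <- function(volume) {
  d <- dim(volume$voxels)
  out <- array(0, dim = c(d[2], d[1], d[3]))
  for (k in seq_len(d[3]))
    out[, , k] <- t(volume$voxels[d[1]:1, , k])
  image_volume(out, volume$spacing[c(2, 1, 3)], volume$origin)
}
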