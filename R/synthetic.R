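#' Cylindrical phantom specification
#'
#' Geometry and nominal HU values of a water cylinder with a coaxial
#' high-contrast insert, modelled on the classic 25 cm water phantom with a
#' 10 cm PTFE rod (nominal 1050 HU at 120 kVp).
#'
#' @param phantom_diameter_mm outer water cylinder diameter (mm).
#' @param insert_diameter_mm insert diameter (mm); must be smaller than the
#'   phantom diameter.
#' @param water_hu,insert_hu,background_hu nominal HU of water, insert and
#'   surrounding air.
#' @param insert_center_mm in-plane (x, y) offset of the insert axis from
#'   the phantom axis, mm.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(phantom_diameter_mm = 250, insert_diameter_mm = 100,
                         water_hu = 0, insert_hu = 1050,
                         background_hu = -1000, insert_center_mm = c(0, 0)) {
  if (insert_diameter_mm >= phantom_diameter_mm)
    stop("insert must be smaller than the phantom")
  r_in <- insert_diameter_mm / 2
  r_ph <- phantom_diameter_mm / 2
  if (sqrt(sum(insert_center_mm^2)) + r_in > r_ph)
    stop("insert must lie fully inside the phantom")
  structure(list(phantom_diameter_mm = phantom_diameter_mm,
                 insert_diameter_mm = insert_diameter_mm,
                 water_hu = water_hu, insert_hu = insert_hu,
                 background_hu = background_hu,
                 insert_center_mm = as.numeric(insert_center_mm)),
            class = "phantom_spec")
}

#' Chest phantom specification
#'
#' Simplified thorax: an elliptic soft-tissue body containing two disjoint
#' ellipsoidal lungs at parenchymal HU, optionally threaded by cylindrical
#' vessels at blood/water HU. Defaults put the parenchyma near -850 HU, the
#' attenuation scale typical of inspiratory lung CT.
#'
#' @param body_hu soft tissue HU.
#' @param lung_hu lung parenchyma HU.
#' @param air_hu HU outside the body.
#' @param vessel_hu HU of intrapulmonary vessels.
#' @param body_semiaxes_mm in-plane body ellipse semi-axes (x, y), mm.
#' @param lung_semiaxes_mm per-lung ellipsoid semi-axes (x, y, z), mm.
#' @param lung_offset_mm lateral (x) offset of each lung centre from the
#'   midline, mm; lungs are mirrored at +/- this offset.
#' @param n_vessels number of vessel cylinders per lung.
#' @param vessel_radius_mm vessel radius, mm.
#' @return A `chest_spec` list.
#' @export
chest_spec <- function(body_hu = 40, lung_hu = -850, air_hu = -1000,
                       vessel_hu = 0,
                       body_semiaxes_mm = c(150, 95),
                       lung_semiaxes_mm = c(55, 65, 40),
                       lung_offset_mm = 70,
                       n_vessels = 3, vessel_radius_mm = 2.5) {
  if (lung_offset_mm - lung_semiaxes_mm[1] < 0)
    stop("lungs overlap: offset smaller than the lateral semi-axis")
  if (lung_offset_mm + lung_semiaxes_mm[1] > body_semiaxes_mm[1] ||
      lung_semiaxes_mm[2] > body_semiaxes_mm[2])
    stop("lungs must lie fully inside the body")
  structure(list(body_hu = body_hu, lung_hu = lung_hu, air_hu = air_hu,
                 vessel_hu = vessel_hu,
                 body_semiaxes_mm = as.numeric(body_semiaxes_mm),
                 lung_semiaxes_mm = as.numeric(lung_semiaxes_mm),
                 lung_offset_mm = lung_offset_mm,
                 n_vessels = n_vessels,
                 vessel_radius_mm = vessel_radius_mm),
            class = "chest_spec")
}

#' Noise model
#'
#' Stationary in-plane noise: either white Gaussian HU noise, or Gaussian
#' noise with a prescribed radial power spectrum (shape given by
#' `radial_profile`, total power by `sigma_hu`).
#'
#' @param kind `"white"` or `"radial_spectrum"`.
#' @param sigma_hu per-voxel noise standard deviation in HU, >= 0.
#' @param radial_profile for `"radial_spectrum"`: a function mapping radial
#'   frequency (1/mm) to relative (nonnegative) power.
#' @param seed integer RNG seed; mandatory so every realization is
#'   reproducible. No global RNG state is consulted.
#' @return A `noise_model` list.
#' @seealso [ramp_bandpass_profile()]
#' @export
noise_model <- function(kind = c("white", "radial_spectrum"), sigma_hu, seed,
                        radial_profile = NULL) {
  kind <- match.arg(kind)
  if (sigma_hu < 0) stop("`sigma_hu` must be >= 0")
  if (missing(seed) || !is.finite(seed)) stop("`seed` is mandatory")
  if (kind == "radial_spectrum" && !is.function(radial_profile))
    stop("`radial_profile` must be a function for kind = 'radial_spectrum'")
  structure(list(kind = kind, sigma_hu = sigma_hu,
                 radial_profile = radial_profile,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Ramp-like band-pass radial noise power profile
#'
#' `P(f) = f * exp(-f^2 / (2 * peak^2))`, a rising-then-falling spectrum
#' whose maximum sits exactly at `peak_freq`. This mimics the band-pass
#' noise texture of reconstructed CT (ramp filter times apodization); the
#' true spectral shape of any given scanner kernel is not modelled.
#'
#' @param peak_freq peak frequency in 1/mm.
#' @return A function of radial frequency.
#' @export
ramp_bandpass_profile <- function(peak_freq = 0.30) {
  force(peak_freq)
  function(f) f * exp(-f^2 / (2 * peak_freq^2))
}

#' Reconstruction-strength emulation levels
#'
#' Image-domain stand-in for an iterative-reconstruction strength setting:
#' each level scales the noise amplitude by `noise_scale` and may add a
#' small extra in-plane blur. It is an emulation of the measured effect of
#' such algorithms on noise magnitude, not a model of any reconstruction.
#'
#' The default scales (1, 0.78, 0.59, 0.43, 0.29) are the phantom
#' noise-magnitude fractions measured for strength levels 1-4 relative to
#' the algorithm switched off; [recon_levels_patient()] carries the
#' in-vivo lung GNI ratios instead.
#'
#' @param noise_scales named numeric vector, one fraction per level, first
#'   level `off` with scale 1; must be non-increasing.
#' @param extra_blur_sigma_mm extra PSF sigma per level (same names), >= 0.
#' @return A `recon_levels` object: data frame with columns `level`,
#'   `noise_scale`, `extra_blur_sigma_mm`.
#' @export
recon_levels <- function(noise_scales = c(off = 1, `1` = 0.78, `2` = 0.59,
                                          `3` = 0.43, `4` = 0.29),
                         extra_blur_sigma_mm = 0) {
  if (is.null(names(noise_scales)) || names(noise_scales)[1] != "off")
    stop("first level must be named 'off'")
  if (noise_scales[["off"]] != 1) stop("noise_scale of level 'off' must be 1")
  if (any(diff(noise_scales) > 1e-12))
    stop("noise scales must be non-increasing with level")
  blur <- rep_len(extra_blur_sigma_mm, length(noise_scales))
  if (any(blur < 0)) stop("extra blur must be >= 0")
  structure(data.frame(level = names(noise_scales),
                       noise_scale = as.numeric(noise_scales),
                       extra_blur_sigma_mm = blur,
                       stringsAsFactors = FALSE),
            class = c("recon_levels", "data.frame"))
}

#' Patient-domain emulation scales
#'
#' Noise fractions equal to the in-vivo lung GNI ratios of strength levels
#' 1-4 relative to off (178, 154, 130, 106 over a 202 HU baseline).
#'
#' @inheritParams recon_levels
#' @return A `recon_levels` object.
#' @export
recon_levels_patient <- function(extra_blur_sigma_mm = 0) {
  recon_levels(c(off = 1, `1` = 178 / 202, `2` = 154 / 202,
                 `3` = 130 / 202, `4` = 106 / 202),
               extra_blur_sigma_mm = extra_blur_sigma_mm)
}

#' Generate a stationary noise volume
#'
#' White noise is i.i.d. Gaussian per voxel. For a radial-spectrum model,
#' white noise is filtered per slice in the 2D frequency domain by the
#' square root of the target radial power profile and then rescaled so the
#' per-slice variance equals `sigma_hu^2` (the profile fixes only the
#' shape). Slices are independent: the spectra of interest are in-plane.
#'
#' @param shape integer (nx, ny, nz).
#' @param spacing (dx, dy, dz) in mm.
#' @param model a [noise_model()].
#' @return An [image_volume] of pure noise.
#' @export
make_noise_field <- function(shape, spacing, model) {
  if (!inherits(model, "noise_model")) stop("`model` must be a noise_model")
  shape <- as.integer(shape)
  rng <- local_rng(model$seed)
  vox <- array(rng$rnorm(prod(shape)), dim = shape)
  if (model$kind == "radial_spectrum") {
    fx <- fft_freq(shape[1], spacing[1])
    fy <- fft_freq(shape[2], spacing[2])
    fr <- sqrt(outer(fx^2, fy^2, "+"))
    p <- model$radial_profile(fr)
    if (any(p < 0) || any(!is.finite(p))) stop("radial profile must be finite and nonnegative")
    if (all(p == 0)) stop("radial profile is identically zero")
    h <- sqrt(p)
    n_px <- shape[1] * shape[2]
    for (k in seq_len(shape[3])) {
      sl <- Re(stats::fft(stats::fft(vox[, , k]) * h, inverse = TRUE)) / n_px
      sl <- sl - mean(sl)
      sd_k <- sqrt(mean(sl^2))
      vox[, , k] <- sl / sd_k
    }
  }
  image_volume(vox * model$sigma_hu, spacing)
}

#' Synthesize a cylindrical water phantom with a high-contrast insert
#'
#' The noiseless signal is the HU map of the geometry (air / water /
#' insert) convolved with an isotropic in-plane Gaussian PSF; a noise
#' realization from `noise` is added afterwards. The same 2D section is
#' extruded along z. Ground-truth masks mark pure-water and pure-insert
#' voxels, eroded 3 PSF sigmas plus one pixel away from every interface so
#' they contain no edge-blurred voxels.
#'
#' @param spec a [phantom_spec()].
#' @param shape integer (nx, ny, nz).
#' @param spacing (dx, dy, dz), mm.
#' @param psf_sigma_mm in-plane Gaussian PSF sigma, >= 0.
#' @param noise a [noise_model()], or NULL for a noiseless volume.
#' @return list with `volume` ([image_volume]), `water_mask`,
#'   `insert_mask` (logical arrays), and `spec`.
#' @export
make_cylinder_phantom <- function(spec, shape, spacing, psf_sigma_mm = 0,
                                  noise = NULL) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  if (psf_sigma_mm < 0) stop("`psf_sigma_mm` must be >= 0")
  shape <- as.integer(shape)
  g <- plane_coords(shape[1], shape[2], spacing)
  r_ph <- spec$phantom_diameter_mm / 2
  fov <- c(shape[1] * spacing[1], shape[2] * spacing[2])
  if (2 * r_ph > min(fov)) stop("phantom exceeds the field of view")
  r_in <- spec$insert_diameter_mm / 2
  rad_ph <- sqrt(g$x^2 + g$y^2)
  rad_in <- sqrt((g$x - spec$insert_center_mm[1])^2 +
                 (g$y - spec$insert_center_mm[2])^2)
  section <- matrix(spec$background_hu, shape[1], shape[2])
  section[rad_ph <= r_ph] <- spec$water_hu
  section[rad_in <= r_in] <- spec$insert_hu
  margin <- 3 * psf_sigma_mm + max(spacing[1:2])
  water2d <- rad_ph <= r_ph - margin & rad_in >= r_in + margin
  insert2d <- rad_in <= r_in - margin
  # geometry is z-invariant: blur one section, then extrude
  sec_vol <- blur_inplane(image_volume(array(section, dim = c(shape[1:2], 1L)),
                                       spacing), psf_sigma_mm)
  vol <- image_volume(array(sec_vol$voxels[, , 1], dim = shape), spacing)
  if (!is.null(noise)) {
    nf <- make_noise_field(shape, spacing, noise)
    vol$voxels <- vol$voxels + nf$voxels
  }
  list(volume = vol,
       water_mask = array(water2d, dim = shape),
       insert_mask = array(insert2d, dim = shape),
       spec = spec)
}

#' Synthesize a chest-like volume with known lung masks
#'
#' Builds the piecewise-constant HU map of a [chest_spec()] (air, body,
#' two ellipsoidal lungs, optional vessel cylinders along z inside the
#' lungs), blurs it in-plane, and adds noise. The returned ground-truth
#' lung mask is the exact set of parenchyma voxels (vessel voxels
#' excluded), taken before any blur.
#'
#' @inheritParams make_cylinder_phantom
#' @param spec a [chest_spec()].
#' @return list with `volume`, `lung_mask` (logical array, parenchyma
#'   only), and `spec`.
#' @export
make_chest_phantom <- function(spec, shape, spacing, psf_sigma_mm = 0,
                               noise = NULL) {
  if (!inherits(spec, "chest_spec")) stop("`spec` must be a chest_spec")
  shape <- as.integer(shape)
  g <- plane_coords(shape[1], shape[2], spacing)
  fov <- c(shape[1] * spacing[1], shape[2] * spacing[2])
  if (2 * spec$body_semiaxes_mm[1] > fov[1] ||
      2 * spec$body_semiaxes_mm[2] > fov[2])
    stop("body exceeds the field of view")
  z <- (seq_len(shape[3]) - (shape[3] + 1) / 2) * spacing[3]
  body2d <- (g$x / spec$body_semiaxes_mm[1])^2 +
            (g$y / spec$body_semiaxes_mm[2])^2 <= 1
  a <- spec$lung_semiaxes_mm
  lung_mask <- array(FALSE, dim = shape)
  vox <- array(spec$air_hu, dim = shape)
  # per-slice ellipse cross-sections of the two mirrored lung ellipsoids
  for (k in seq_len(shape[3])) {
    s2 <- 1 - (z[k] / a[3])^2
    sl <- matrix(spec$air_hu, shape[1], shape[2])
    sl[body2d] <- spec$body_hu
    if (s2 > 0) {
      lungL <- ((g$x + spec$lung_offset_mm) / a[1])^2 +
               (g$y / a[2])^2 <= s2
      lungR <- ((g$x - spec$lung_offset_mm) / a[1])^2 +
               (g$y / a[2])^2 <= s2
      lung_k <- lungL | lungR
      sl[lung_k] <- spec$lung_hu
      vessel_k <- matrix(FALSE, shape[1], shape[2])
      if (spec$n_vessels > 0) {
        for (side in c(-1, 1)) {
          for (v in seq_len(spec$n_vessels)) {
            ang <- 2 * pi * (v - 1) / spec$n_vessels
            cx <- side * spec$lung_offset_mm + 0.45 * a[1] * cos(ang)
            cy <- 0.45 * a[2] * sin(ang)
            vessel_k <- vessel_k |
              ((g$x - cx)^2 + (g$y - cy)^2 <= spec$vessel_radius_mm^2)
          }
        }
      }
      vessel_k <- vessel_k & lung_k
      sl[vessel_k] <- spec$vessel_hu
      lung_mask[, , k] <- lung_k & !vessel_k
    }
    vox[, , k] <- sl
  }
  vol <- blur_inplane(image_volume(vox, spacing), psf_sigma_mm)
  if (!is.null(noise)) {
    nf <- make_noise_field(shape, spacing, noise)
    vol$voxels <- vol$voxels + nf$voxels
  }
  list(volume = vol, lung_mask = lung_mask, spec = spec)
}

#' Emulate a reconstruction strength level
#'
#' `output = blur(signal) + noise_scale * blur(noise)`: the level's extra
#' PSF acts on both the deterministic signal and the noise (a smoothing
#' reconstruction lowers the noise band-pass too), and the noise amplitude
#' is multiplied by the level's fraction. Level `off` (scale 1, blur 0)
#' returns `signal + noise` unchanged.
#'
#' @param signal noiseless [image_volume].
#' @param noise zero-mean noise [image_volume] with identical shape and
#'   spacing.
#' @param levels a [recon_levels()] object.
#' @param level level name (a row of `levels`).
#' @return An [image_volume].
#' @export
emulate_reconstruction <- function(signal, noise, levels, level = "off") {
  stopifnot_volume(signal); stopifnot_volume(noise)
  if (!identical(dim(signal$voxels), dim(noise$voxels)) ||
      max(abs(signal$spacing - noise$spacing)) > 1e-9)
    stop("signal and noise must share shape and spacing")
  row <- levels[levels$level == level, ]
  if (nrow(row) != 1L) stop("unknown level: ", level)
  if (row$extra_blur_sigma_mm == 0 && row$noise_scale == 1) {
    out <- signal
    out$voxels <- signal$voxels + noise$voxels
    return(out)
  }
  s <- blur_inplane(signal, row$extra_blur_sigma_mm)
  n <- blur_inplane(noise, row$extra_blur_sigma_mm)
  image_volume(s$voxels + row$noise_scale * n$voxels,
               signal$spacing, signal$origin)
}

# Self-contained RNG: draws from a private stream seeded with `seed`,
# leaving the caller's .Random.seed untouched.
local_rng <- function(seed) {
  env <- new.env()
  list(rnorm = function(n, mean = 0, sd = 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
    if (!is.null(env$state)) assign(".Random.seed", env$state, globalenv())
    else set.seed(seed)
    out <- stats::rnorm(n, mean, sd)
    env$state <- get(".Random.seed", globalenv())
    out
  })
}
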