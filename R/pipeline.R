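#' Default phantom-study configuration
#'
#' The noise (NPS) arm measures a homogeneous water stack of `n_slices_nps`
#' slices at the ROI size used for spectrum estimation; the resolution
#' (TTF) arm images a high-contrast insert on a fine ultra-high-resolution
#' grid. Problem sizes are chosen so a full study runs in well under a
#' minute on one core while every estimator still operates in its
#' asymptotic regime.
#'
#' @param seed integer seed for the noise realizations.
#' @param levels a [recon_levels()] table.
#' @param nps_peak_freq target radial NPS peak frequency (1/mm) of the
#'   generated noise.
#' @param nps_sigma_hu noise magnitude of the NPS arm (HU).
#' @param n_slices_nps slices (= averaged ROIs) in the NPS arm.
#' @param nps_pixel_mm in-plane pixel pitch of the NPS arm.
#' @param roi_size_px NPS ROI side length (pixels).
#' @param ttf_pixel_mm pixel pitch of the TTF arm.
#' @param ttf_psf_sigma_mm system PSF sigma of the TTF arm.
#' @param ttf_sigma_hu noise magnitude of the TTF arm (kept below 2% of
#'   the 1050 HU insert contrast, where the TTF estimate is noise-stable).
#' @param n_slices_ttf slices pooled in the TTF arm.
#' @return config list.
#' @export
phantom_study_config <- function(seed,
                                 levels = recon_levels(),
                                 nps_peak_freq = 0.30,
                                 nps_sigma_hu = 100,
                                 n_slices_nps = 100,
                                 nps_pixel_mm = 0.586,
                                 roi_size_px = 270,
                                 ttf_pixel_mm = 0.2,
                                 ttf_psf_sigma_mm = 0.5,
                                 ttf_sigma_hu = 15,
                                 n_slices_ttf = 6) {
  list(seed = as.integer(seed), levels = levels,
       nps_peak_freq = nps_peak_freq, nps_sigma_hu = nps_sigma_hu,
       n_slices_nps = n_slices_nps, nps_pixel_mm = nps_pixel_mm,
       roi_size_px = roi_size_px, ttf_pixel_mm = ttf_pixel_mm,
       ttf_psf_sigma_mm = ttf_psf_sigma_mm, ttf_sigma_hu = ttf_sigma_hu,
       n_slices_ttf = n_slices_ttf)
}

#' Run the phantom arm: NPS and TTF per reconstruction level
#'
#' Generates one fixed noise realization, emulates every reconstruction
#' level from it, and measures per level the radial NPS (noise magnitude,
#' peak frequency, peak shift vs level `off`) and the sector-averaged TTF
#' (TTF50/TTF10 and their shifts vs level `off`).
#'
#' @param config from [phantom_study_config()].
#' @return list with `noise_table` (level, noise_magnitude_hu,
#'   fraction_pct, peak_frequency, peak_shift_pct), `ttf_table` (level,
#'   ttf50, ttf10, ttf50_shift_pct, ttf10_shift_pct), `spectra`, `ttfs`,
#'   and the `config` echo.
#' @export
run_phantom_study <- function(config) {
  lv <- config$levels
  # --- noise arm: homogeneous water stack at ROI size
  shape_n <- c(config$roi_size_px, config$roi_size_px, config$n_slices_nps)
  sp_n <- c(config$nps_pixel_mm, config$nps_pixel_mm, 1.5)
  water <- image_volume(array(0, dim = shape_n), sp_n)
  nm <- noise_model("radial_spectrum", sigma_hu = config$nps_sigma_hu,
                    seed = config$seed,
                    radial_profile = ramp_bandpass_profile(config$nps_peak_freq))
  noise_n <- make_noise_field(shape_n, sp_n, nm)
  spectra <- list()
  for (l in lv$level) {
    vol <- emulate_reconstruction(water, noise_n, lv, l)
    spectra[[l]] <- radial_average(compute_nps2d(vol,
                                                 roi_size_px = config$roi_size_px))
  }
  ref <- spectra[["off"]]
  noise_table <- data.frame(
    level = lv$level,
    noise_magnitude_hu = vapply(spectra, function(s) s$noise_magnitude,
                                numeric(1)),
    peak_frequency = vapply(spectra, function(s) s$peak_frequency,
                            numeric(1)),
    stringsAsFactors = FALSE)
  noise_table$fraction_pct <- 100 * noise_table$noise_magnitude_hu /
    ref$noise_magnitude
  noise_table$peak_shift_pct <- vapply(spectra, peak_shift, numeric(1),
                                       reference = ref)
  # --- resolution arm: insert on a fine grid
  fov_px <- 384L
  shape_t <- c(fov_px, fov_px, config$n_slices_ttf)
  sp_t <- c(config$ttf_pixel_mm, config$ttf_pixel_mm, 1.5)
  spec_t <- phantom_spec(phantom_diameter_mm = 72, insert_diameter_mm = 50)
  ph <- make_cylinder_phantom(spec_t, shape_t, sp_t,
                              psf_sigma_mm = config$ttf_psf_sigma_mm)
  noise_t <- make_noise_field(shape_t, sp_t,
                              noise_model("white", config$ttf_sigma_hu,
                                          seed = config$seed + 1L))
  ttfs <- list()
  for (l in lv$level) {
    vol <- emulate_reconstruction(ph$volume, noise_t, lv, l)
    ttfs[[l]] <- measure_ttf(vol)
  }
  tref <- ttfs[["off"]]
  shifts <- t(vapply(ttfs, ttf_landmarks_and_shift, numeric(2),
                     reference = tref))
  ttf_table <- data.frame(
    level = lv$level,
    ttf50 = vapply(ttfs, function(x) x$ttf50, numeric(1)),
    ttf10 = vapply(ttfs, function(x) x$ttf10, numeric(1)),
    ttf50_shift_pct = shifts[, 1], ttf10_shift_pct = shifts[, 2],
    stringsAsFactors = FALSE)
  list(noise_table = noise_table, ttf_table = ttf_table,
       spectra = spectra, ttfs = ttfs, config = config)
}

#' Calibrate the extra blur that produces a target NPS peak shift
#'
#' Bisection on the emulation blur sigma: each candidate blurs a fixed
#' band-pass noise realization, measures the radial NPS peak, and
#' compares the percent shift against the unblurred reference. The shift
#' is monotone decreasing in sigma, so bisection converges.
#'
#' @param target_shift_pct desired (negative) percent peak shift.
#' @param peak_freq noise peak frequency (1/mm).
#' @param pixel_mm in-plane pixel pitch.
#' @param n_slices slices in the calibration stack.
#' @param roi_size_px ROI size.
#' @param seed noise seed.
#' @param sigma_hi upper bracket for the blur sigma (mm).
#' @param tol_pct convergence tolerance on the shift (percentage points).
#' @return list `blur_sigma_mm`, `achieved_shift_pct`.
#' @export
calibrate_blur_for_peak_shift <- function(target_shift_pct = -6.7,
                                          peak_freq = 0.30,
                                          pixel_mm = 0.586, n_slices = 60,
                                          roi_size_px = 128, seed = 1,
                                          sigma_hi = 1.0, tol_pct = 0.05) {
  if (target_shift_pct >= 0) stop("target shift must be negative")
  shape <- c(roi_size_px, roi_size_px, n_slices)
  sp <- c(pixel_mm, pixel_mm, 1.5)
  nm <- noise_model("radial_spectrum", sigma_hu = 100, seed = seed,
                    radial_profile = ramp_bandpass_profile(peak_freq))
  noise <- make_noise_field(shape, sp, nm)
  ref <- radial_average(compute_nps2d(noise, roi_size_px = roi_size_px))
  shift_at <- function(sigma) {
    b <- blur_inplane(noise, sigma)
    peak_shift(radial_average(compute_nps2d(b, roi_size_px = roi_size_px)),
               ref)
  }
  lo <- 0; hi <- sigma_hi
  s_hi <- shift_at(hi)
  if (s_hi > target_shift_pct)
    stop("`sigma_hi` bracket too small for the requested shift")
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    s <- shift_at(mid)
    if (abs(s - target_shift_pct) < tol_pct) {
      return(list(blur_sigma_mm = mid, achieved_shift_pct = s))
    }
    if (s > target_shift_pct) lo <- mid else hi <- mid
  }
  list(blur_sigma_mm = mid, achieved_shift_pct = s)
}

#' Default cohort-study configuration
#'
#' Synthetic chest cases emulating a low-dose sharp-kernel lung protocol:
#' parenchyma at -850 HU, per-case baseline noise drawn from a normal
#' distribution with mean 202 HU and SD 34 HU (the across-patient spread
#' of the baseline lung noise index this emulation targets), mild
#' per-case variation of lung size, and the patient-domain level scales
#' of [recon_levels_patient()].
#'
#' @param seed integer master seed; per-case seeds derive from it.
#' @param n_cases number of synthetic cases (>= 3).
#' @param levels a [recon_levels()] table.
#' @param shape,spacing volume geometry.
#' @param psf_sigma_mm system PSF of the generated signal.
#' @param gni_mean_hu,gni_sd_hu distribution of per-case baseline noise.
#' @param kernel_radius_vox,min_kernel_count local-statistics kernel.
#' @param noise_bin_hu,snr_bin histogram bin widths for GNI / GSNRI.
#' @param erosion_mm mask erosion before metric computation.
#' @return config list.
#' @export
cohort_study_config <- function(seed, n_cases = 10,
                                levels = recon_levels_patient(),
                                shape = c(256, 256, 40),
                                spacing = c(1.4, 1.4, 2.5),
                                psf_sigma_mm = 0.6,
                                gni_mean_hu = 202, gni_sd_hu = 34,
                                kernel_radius_vox = 2, min_kernel_count = 15,
                                noise_bin_hu = 1.0, snr_bin = 0.1,
                                erosion_mm = 2) {
  list(seed = as.integer(seed), n_cases = n_cases, levels = levels,
       shape = shape, spacing = spacing, psf_sigma_mm = psf_sigma_mm,
       gni_mean_hu = gni_mean_hu, gni_sd_hu = gni_sd_hu,
       kernel_radius_vox = kernel_radius_vox,
       min_kernel_count = min_kernel_count,
       noise_bin_hu = noise_bin_hu, snr_bin = snr_bin,
       erosion_mm = erosion_mm)
}

case_seed <- function(master, case) {
  as.integer((as.numeric(master) * 1009 + case * 7919) %% 2147483629)
}

#' Run the cohort arm: global indices per case and level
#'
#' For each synthetic case: generate the chest signal and one baseline
#' noise realization, emulate every reconstruction level, segment the
#' lungs once on the level-`off` volume (the mask is reused across
#' levels so comparisons are not confounded by mask jitter), erode the
#' mask for metric computation, and compute GNI, GSNRI and mean
#' attenuation per level. The per-level summaries and the paired
#' nonparametric comparisons (Friedman + Wilcoxon, BH-adjusted) are
#' returned for GNI and GSNRI.
#'
#' @param config from [cohort_study_config()].
#' @return list with `per_case` (data frame: case, level, gni_hu, gsnri,
#'   mean_attenuation_hu, n_voxels, dice_vs_truth), `summary`
#'   (from [compare_reconstructions()]), `tests_gni`, `tests_gsnri`,
#'   `config`.
#' @export
run_cohort_study <- function(config) {
  if (config$n_cases < 3) stop("need at least 3 cases")
  lv <- config$levels
  rows <- list()
  for (ci in seq_len(config$n_cases)) {
    cs <- case_seed(config$seed, ci)
    rngv <- local_rng(cs)
    draw <- rngv$rnorm(4)
    size_jitter <- 1 + 0.08 * pmax(pmin(draw[1:3], 2), -2) / 2
    sigma_case <- max(50, config$gni_mean_hu + config$gni_sd_hu * draw[4])
    spec <- chest_spec(lung_semiaxes_mm = c(55, 65, 40) * size_jitter)
    chest <- make_chest_phantom(spec, config$shape, config$spacing,
                                psf_sigma_mm = config$psf_sigma_mm)
    noise <- make_noise_field(config$shape, config$spacing,
                              noise_model("white", sigma_case,
                                          seed = cs + 1L))
    vol_off <- emulate_reconstruction(chest$volume, noise, lv, "off")
    mask <- segment_lungs(vol_off)
    dice <- dice_coefficient(array(as.logical(mask), dim = config$shape),
                             chest$lung_mask)
    mask_m <- erode_for_metrics(mask, config$erosion_mm, config$spacing)
    for (l in lv$level) {
      vol <- emulate_reconstruction(chest$volume, noise, lv, l)
      st <- local_stats(vol, mask_m, config$kernel_radius_vox,
                        config$min_kernel_count)
      gi <- global_indices(vol, mask_m, st, config$noise_bin_hu,
                           config$snr_bin)
      rows[[length(rows) + 1L]] <- data.frame(
        case = ci, level = l, gni_hu = gi$gni_hu, gsnri = gi$gsnri,
        mean_attenuation_hu = gi$mean_attenuation_hu,
        n_voxels = gi$n_voxels, dice_vs_truth = dice,
        stringsAsFactors = FALSE)
    }
  }
  per_case <- do.call(rbind, rows)
  summary <- compare_reconstructions(per_case)
  mk <- function(col) data.frame(case = per_case$case,
                                 level = per_case$level,
                                 value = per_case[[col]])
  list(per_case = per_case, summary = summary,
       tests_gni = paired_level_tests(mk("gni_hu"), "nonparametric"),
       tests_gsnri = paired_level_tests(mk("gsnri"), "nonparametric"),
       config = config)
}
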