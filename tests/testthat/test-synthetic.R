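test_that("cylinder phantom hits nominal HU values and is z-invariant", {
  ph <- make_cylinder_phantom(phantom_spec(), shape = c(192, 192, 3),
                              spacing = c(1.5, 1.5, 1.5))
  d <- dim(ph$volume$voxels)
  ctr <- d[1] %/% 2
  expect_equal(ph$volume$voxels[ctr, ctr, 1], 1050)
  expect_true(any(ph$water_mask))
  expect_true(all(abs(ph$volume$voxels[, , 1][ph$water_mask[, , 1]]) < 1e-9))
  expect_equal(ph$volume$voxels[, , 1], ph$volume$voxels[, , 3])
  expect_error(make_cylinder_phantom(phantom_spec(), shape = c(64, 64, 2),
                                     spacing = c(1.5, 1.5, 1.5)),
               "field of view")
})

test_that("phantom spec rejects inconsistent geometry", {
  expect_error(phantom_spec(insert_diameter_mm = 300), "smaller")
  expect_error(phantom_spec(insert_center_mm = c(80, 0)), "inside")
})

test_that("blurred insert edge follows the Gaussian error-function profile", {
  ph <- ttf_phantom(psf_sigma_mm = 0.5, n_slices = 1)
  esf <- extract_radial_esf(ph$volume, c(0, 0), 25, slice_range = 1)[[1]]
  pred <- 1050 * pnorm(-esf$positions / 0.5)
  # pointwise agreement limited by within-bin radius spread at the
  # steepest point (~2% of contrast); median far tighter
  expect_lt(max(abs(esf$hu - pred)), 0.025 * 1050)
  expect_lt(median(abs(esf$hu - pred)), 1)
})

test_that("white noise field has the requested amplitude and reproduces bitwise", {
  nf <- white_stack(10, seed = 11, n_px = 128, n_slices = 100)
  expect_equal(sd(as.vector(nf$voxels)), 10, tolerance = 0.01)
  nf2 <- white_stack(10, seed = 11, n_px = 128, n_slices = 100)
  expect_identical(nf$voxels, nf2$voxels)
  zero <- white_stack(0, seed = 11, n_px = 16, n_slices = 2)
  expect_true(all(zero$voxels == 0))
})

test_that("noise generation does not disturb the caller's RNG stream", {
  set.seed(42); a <- rnorm(1)
  set.seed(42); invisible(white_stack(5, seed = 3, n_px = 16, n_slices = 2))
  b <- rnorm(1)
  expect_identical(a, b)
})

test_that("radial-spectrum noise matches the requested variance and peak", {
  nm <- noise_model("radial_spectrum", sigma_hu = 50, seed = 7,
                    radial_profile = ramp_bandpass_profile(0.30))
  nf <- make_noise_field(c(270, 270, 30), c(0.586, 0.586, 1.5), nm)
  for (k in c(1, 15)) {
    expect_equal(sd(as.vector(nf$voxels[, , k])), 50, tolerance = 0.01)
  }
  rs <- radial_average(compute_nps2d(nf, roi_size_px = 270))
  expect_equal(rs$peak_frequency, 0.30, tolerance = 0.05)
  expect_error(make_noise_field(c(16, 16, 2), c(1, 1, 1),
                                noise_model("radial_spectrum", 10, seed = 1,
                                            radial_profile = function(f) 0 * f)),
               "zero")
})

test_that("chest phantom lung mask is exact and excludes vessels", {
  ch <- small_chest(psf_sigma_mm = 0)
  expect_true(all(ch$volume$voxels[ch$lung_mask] == -850))
  # vessels are inside the lung geometry but not in the parenchyma mask
  vessel_vox <- ch$volume$voxels == 0 &
    array(TRUE, dim(ch$volume$voxels))
  expect_true(any(vessel_vox))
  expect_false(any(ch$lung_mask & vessel_vox))
  expect_error(chest_spec(lung_offset_mm = 30), "overlap")
})

test_that("emulation level off is the exact identity", {
  ph <- small_chest(psf_sigma_mm = 0.6)
  nf <- make_noise_field(dim(ph$volume$voxels), ph$volume$spacing,
                         noise_model("white", 100, seed = 5))
  lv <- recon_levels()
  out <- emulate_reconstruction(ph$volume, nf, lv, "off")
  expect_identical(out$voxels, ph$volume$voxels + nf$voxels)
  bad <- image_volume(array(0, c(4, 4, 2)), ph$volume$spacing)
  expect_error(emulate_reconstruction(ph$volume, bad, lv, "off"), "shape")
})

test_that("measured noise magnitude decreases strictly across levels", {
  lv <- recon_levels()
  water <- image_volume(array(0, c(128, 128, 40)), c(0.586, 0.586, 1.5))
  nf <- make_noise_field(dim(water$voxels), water$spacing,
                         noise_model("white", 80, seed = 9))
  mags <- vapply(lv$level, function(l) {
    v <- emulate_reconstruction(water, nf, lv, l)
    radial_average(compute_nps2d(v, roi_size_px = 128))$noise_magnitude
  }, numeric(1))
  expect_true(all(diff(mags) < 0))
  expect_equal(unname(mags / mags[1]), lv$noise_scale, tolerance = 1e-6)
})

test_that("recon level tables enforce their invariants", {
  expect_error(recon_levels(c(off = 1, `1` = 1.1)), "non-increasing")
  expect_error(recon_levels(c(a = 1, b = 0.5)), "off")
  lv <- recon_levels_patient()
  expect_equal(lv$noise_scale[5], 106 / 202)
})
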