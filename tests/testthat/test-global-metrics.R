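test_that("local stats are exact on a constant region", {
  vox <- array(-850, c(32, 32, 4))
  v <- image_volume(vox, c(1, 1, 2))
  mask <- array(TRUE, dim(vox))
  st <- local_stats(v, mask)
  defined <- !is.na(st$local_sd_hu)
  expect_true(any(defined))
  expect_true(all(st$local_sd_hu[defined] == 0))
  expect_true(all(st$local_mean_hu[defined] == -850))
  expect_error(local_stats(v, array(FALSE, dim(vox))), "empty")
  expect_error(local_stats(v, mask, kernel_radius_vox = 0), "kernel")
})

test_that("local SD recovers the noise level of white noise", {
  nf <- white_stack(20, seed = 51, n_px = 96, n_slices = 6, pixel_mm = 1)
  mask <- array(TRUE, dim(nf$voxels))
  st <- local_stats(nf, mask)
  med <- median(st$local_sd_hu, na.rm = TRUE)
  expect_equal(med, 20, tolerance = 0.05)
})

test_that("kernel truncation respects the mask and the minimum count", {
  nf <- white_stack(10, seed = 52, n_px = 32, n_slices = 2, pixel_mm = 1)
  mask <- array(FALSE, dim(nf$voxels))
  mask[10:20, 10:20, ] <- TRUE
  # a lone voxel far from the block: kernel has 1 < 15 voxels -> NA
  mask[30, 30, 1] <- TRUE
  st <- local_stats(nf, mask)
  expect_true(is.na(st$local_sd_hu[30, 30, 1]))
  expect_false(is.na(st$local_sd_hu[15, 15, 1]))
  expect_true(all(is.na(st$local_sd_hu[!mask])))
})

test_that("histogram mode finds constants, Gaussian centres and heavier modes", {
  expect_equal(histogram_mode(rep(3.25, 5000), 1), 3.25)
  set.seed(53)
  expect_equal(histogram_mode(rnorm(1e6, 106, 18), 1), 106, tolerance = 1)
  set.seed(54)
  bimodal <- c(rnorm(4e5, 80, 15), rnorm(6e5, 130, 10))
  expect_equal(histogram_mode(bimodal, 1), 130, tolerance = 2)
  expect_error(histogram_mode(numeric(0), 1), "no values")
  expect_warning(histogram_mode(rnorm(100), 0.5), "1000")
})

test_that("global indices recover noise level, SNR and attenuation", {
  ch <- small_chest(n_vessels = 0, psf_sigma_mm = 0.6)
  mask <- erode_for_metrics(segment_lungs(ch$volume), 2,
                            ch$volume$spacing)
  nf <- make_noise_field(dim(ch$volume$voxels), ch$volume$spacing,
                         noise_model("white", 202, seed = 55))
  v <- ch$volume; v$voxels <- v$voxels + nf$voxels
  st <- local_stats(v, mask)
  gi <- global_indices(v, mask, st)
  expect_equal(gi$gni_hu, 202, tolerance = 0.05 * 202)
  expect_equal(gi$gsnri, 850 / 202, tolerance = 0.05 * 850 / 202)
  expect_equal(gi$mean_attenuation_hu, -850, tolerance = 3)
  expect_equal(sum(gi$noise_histogram$counts), gi$n_voxels)
  # noise-free constant volume: every local SD is 0, SNR undefined
  v0 <- image_volume(array(-850, dim(ch$volume$voxels)),
                     ch$volume$spacing)
  st0 <- local_stats(v0, mask)
  expect_error(global_indices(v0, mask, st0), "SNR")
})

test_that("GNI scales with the noise and ignores HU offsets", {
  ch <- small_chest(n_vessels = 0, psf_sigma_mm = 0.6)
  mask <- erode_for_metrics(segment_lungs(ch$volume), 2,
                            ch$volume$spacing)
  nf <- make_noise_field(dim(ch$volume$voxels), ch$volume$spacing,
                         noise_model("white", 150, seed = 56))
  v <- ch$volume; v$voxels <- v$voxels + nf$voxels
  gi <- global_indices(v, mask, local_stats(v, mask))
  v2 <- ch$volume; v2$voxels <- v2$voxels + 0.525 * nf$voxels
  gi2 <- global_indices(v2, mask, local_stats(v2, mask))
  expect_equal(gi2$gni_hu / gi$gni_hu, 0.525, tolerance = 0.02 * 0.525)
  expect_equal(gi$gsnri / gi2$gsnri, 0.525, tolerance = 0.03)
  v3 <- v; v3$voxels <- v3$voxels + 100
  gi3 <- global_indices(v3, mask, local_stats(v3, mask))
  expect_equal(gi3$gni_hu, gi$gni_hu, tolerance = 1e-3)
  expect_equal(gi3$mean_attenuation_hu, gi$mean_attenuation_hu + 100,
               tolerance = 1e-9)
})

test_that("level comparison table reports the printed percent changes", {
  res <- data.frame(case = 1, level = c("off", "4"),
                    gni_hu = c(202, 106), gsnri = c(4.4, 8.2),
                    mean_attenuation_hu = c(-849, -852))
  cmp <- compare_reconstructions(res)
  expect_equal(cmp$gni_change_pct[2], -47.5, tolerance = 0.05)
  expect_equal(cmp$gsnri_change_pct[2], 86.9, tolerance = 0.15)
  same <- data.frame(case = rep(1:3, 2),
                     level = rep(c("off", "2"), each = 3),
                     gni_hu = 100, gsnri = 5, mean_attenuation_hu = -850)
  cmp2 <- compare_reconstructions(same)
  expect_true(all(cmp2$gni_change_pct == 0))
  bad <- res; bad$case <- c(1, 2)
  expect_error(compare_reconstructions(bad), "case sets")
})
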