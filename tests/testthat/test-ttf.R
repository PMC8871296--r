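test_that("insert edge is located with subvoxel precision", {
  ph <- ttf_phantom(psf_sigma_mm = 0, n_slices = 1)
  fit <- fit_insert_edge(ph$volume)
  expect_lt(max(abs(fit$center_xy_mm)), 0.1 * 0.2)   # 0.1 px
  expect_equal(fit$radius_mm, 25, tolerance = 0.1)
  expect_equal(fit$inner_hu - fit$outer_hu, 1050, tolerance = 10)
})

test_that("edge search fails on a flat water volume", {
  flat <- image_volume(array(0, c(64, 64, 2)), c(0.5, 0.5, 1.5))
  expect_error(fit_insert_edge(flat), "no high-contrast insert")
})

test_that("default sector scheme yields 72 profiles at 5-degree centres", {
  ph <- ttf_phantom(psf_sigma_mm = 0.5, n_slices = 1)
  esfs <- extract_radial_esf(ph$volume, c(0, 0), 25, slice_range = 1)
  expect_length(esfs, 72)
  expect_equal(vapply(esfs, function(e) e$sector_angle_deg, numeric(1)),
               5 * (0:71))
  for (e in esfs[c(1, 36)]) {
    expect_true(all(diff(e$positions) > 0))
    expect_lt(min(e$positions), -6)
    expect_gt(max(e$positions), 6)
  }
  expect_error(extract_radial_esf(ph$volume, c(0, 0), 25, n_sectors = 10,
                                  sector_step_deg = 5), "360")
})

test_that("a sharp edge gives a step ESF and a high TTF across the pixel band", {
  ph <- ttf_phantom(psf_sigma_mm = 0, n_slices = 1)
  esf <- extract_radial_esf(ph$volume, c(0, 0), 25, slice_range = 1)[[1]]
  # plateau-to-plateau transition within ~one pixel of r = 0
  inside <- esf$positions < -0.25
  outside <- esf$positions > 0.25
  expect_true(all(abs(esf$hu[inside] - 1050) < 1))
  expect_true(all(abs(esf$hu[outside]) < 1))
  tc <- esf_to_ttf(esf, smooth = FALSE)
  # high modulation over the half pixel-Nyquist band (pixel 0.2 mm)
  expect_true(all(tc$modulation[tc$frequencies <= 1.25] > 0.95))
})

test_that("an ideal step ESF reproduces the central-difference transfer exactly", {
  dr <- 0.02
  pos <- seq(-8 + dr / 2, 8 - dr / 2, by = dr)
  step <- structure(list(positions = pos,
                         hu = ifelse(pos < 0, 1050, 0),
                         sector_angle_deg = 0,
                         n_samples = rep(1L, length(pos)),
                         bin_width_mm = dr),
                    class = "esf_profile")
  ts <- esf_to_ttf(step, smooth = FALSE)
  expect_equal(ts$contrast_hu, 1050)
  # two-impulse LSF: |cos(pi f dr)|, ~1 over any band well below Nyquist
  expect_equal(ts$modulation, abs(cos(pi * ts$frequencies * dr)),
               tolerance = 1e-12)
  expect_true(all(ts$modulation[ts$frequencies <= 5] > 0.95))
})

test_that("Gaussian blur TTF matches the analytic MTF and landmarks", {
  ph <- ttf_phantom(psf_sigma_mm = 0.5, n_slices = 2)
  tc <- measure_ttf(ph$volume)
  expect_equal(tc$contrast_hu, 1050, tolerance = 10)
  keep <- tc$frequencies <= tc$ttf10
  expect_lt(max(abs(tc$modulation[keep] -
                      gaussian_mtf(tc$frequencies[keep], 0.5))), 0.02)
  expect_equal(tc$ttf50, gaussian_mtf_landmark(0.5, 0.5), tolerance = 0.03 *
                 gaussian_mtf_landmark(0.5, 0.5))
  expect_equal(tc$ttf10, gaussian_mtf_landmark(0.5, 0.1), tolerance = 0.03 *
                 gaussian_mtf_landmark(0.5, 0.1))
  expect_gt(tc$ttf10, tc$ttf50)
})

test_that("TTF50 follows the 1/sigma scaling law", {
  t05 <- measure_ttf(ttf_phantom(psf_sigma_mm = 0.5, n_slices = 1)$volume)
  t10 <- measure_ttf(ttf_phantom(psf_sigma_mm = 1.0, n_slices = 1)$volume)
  expect_equal(t10$ttf50, t05$ttf50 / 2, tolerance = 0.02 * t05$ttf50 / 2)
})

test_that("TTF is stable under noise at high contrast and under translation", {
  noise <- noise_model("white", 15, seed = 31)   # < 2% of 1050 HU contrast
  tn <- measure_ttf(ttf_phantom(psf_sigma_mm = 0.5, n_slices = 2,
                                noise = noise)$volume)
  t0 <- measure_ttf(ttf_phantom(psf_sigma_mm = 0.5, n_slices = 2)$volume)
  expect_equal(tn$ttf50, t0$ttf50, tolerance = 0.02 * t0$ttf50)
  # translated insert (kept small enough that the ESF window stays in
  # the water annulus)
  sp <- phantom_spec(phantom_diameter_mm = 72, insert_diameter_mm = 50,
                     insert_center_mm = c(1.5, -1.0))
  ph <- make_cylinder_phantom(sp, c(384, 384, 1), c(0.2, 0.2, 1.5),
                              psf_sigma_mm = 0.5)
  fit <- fit_insert_edge(ph$volume)
  expect_equal(fit$center_xy_mm, c(1.5, -1.0), tolerance = 0.05)
  tt <- measure_ttf(ph$volume)
  expect_equal(tt$ttf50, t0$ttf50, tolerance = 0.02 * t0$ttf50)
})

test_that("averaging identical curves is the identity; mixtures lie between", {
  ph <- ttf_phantom(psf_sigma_mm = 0.5, n_slices = 1)
  esfs <- extract_radial_esf(ph$volume, c(0, 0), 25, slice_range = 1)
  curves <- lapply(esfs[1:4], esf_to_ttf)
  same <- average_ttf(rep(curves[1], 5))
  expect_equal(same$modulation, curves[[1]]$modulation, tolerance = 1e-12)
  expect_equal(same$ttf50, curves[[1]]$ttf50, tolerance = 1e-9)
  # isotropic blur: sector-averaged curve close to any single sector
  avg <- average_ttf(curves)
  expect_equal(avg$modulation[avg$frequencies <= avg$ttf10],
               curves[[2]]$modulation[curves[[2]]$frequencies <= avg$ttf10],
               tolerance = 0.01)
  # mean of two analytic MTFs lies strictly between them
  f <- seq(0.01, 1.5, by = 0.01)
  c04 <- lungiq:::new_ttf_curve(f, gaussian_mtf(f, 0.4), 1000)
  c06 <- lungiq:::new_ttf_curve(f, gaussian_mtf(f, 0.6), 1000)
  mix <- average_ttf(list(c04, c06))
  expect_true(all(mix$modulation < c04$modulation + 1e-12))
  expect_true(all(mix$modulation > c06$modulation - 1e-12))
  expect_error(average_ttf(list(c04, lungiq:::new_ttf_curve(f + 0.1,
    gaussian_mtf(f, 0.4), 1000))), "grid")
})

test_that("landmark shifts match their definition and blur lowers both", {
  f <- seq(0.005, 2.4, by = 0.005)
  ref <- lungiq:::new_ttf_curve(f, gaussian_mtf(f, 0.5), 1050)
  test <- lungiq:::new_ttf_curve(f, gaussian_mtf(f, 0.5 / 0.98), 1050)
  s <- ttf_landmarks_and_shift(test, ref)
  expect_equal(unname(s[1]), -2.0, tolerance = 0.05)
  expect_equal(unname(ttf_landmarks_and_shift(ref, ref)),
               c(0, 0), tolerance = 1e-9)
  blurred <- lungiq:::new_ttf_curve(f, gaussian_mtf(f, 0.7), 1050)
  sb <- ttf_landmarks_and_shift(blurred, ref)
  expect_true(all(sb < 0))
})

test_that("degenerate ESFs are rejected", {
  ph <- ttf_phantom(psf_sigma_mm = 0.5, n_slices = 1)
  esf <- extract_radial_esf(ph$volume, c(0, 0), 25, slice_range = 1)[[1]]
  inverted <- esf
  inverted$hu <- rev(esf$hu)
  expect_error(esf_to_ttf(inverted), "contrast")
  f <- seq(0.01, 0.3, by = 0.01)
  flat <- lungiq:::new_ttf_curve
  expect_error(flat(f, rep(0.9, length(f)), 100), "never crosses")
})
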