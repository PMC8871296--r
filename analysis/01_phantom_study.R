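#!/usr/bin/env Rscript

# Phantom arm: how do emulated reconstruction-strength levels change the
# noise power spectrum and the high-contrast TTF?
#
# One band-pass noise realization (peak 0.30 /mm, the texture of a sharp
# lung kernel) is scaled per level by the measured phantom fractions
# (100/78/59/43/29 %); the insert arm measures the sector-averaged TTF
# of a 1050 HU insert under a 0.5 mm Gaussian system PSF. A second pass
# adds to level 4 the extra blur calibrated to shift the NPS peak by
# -6.7 %, the signature of the strongest reconstruction level.
#
# Findings with seed 101: the measured noise-magnitude fractions land on
# the programmed 78/59/43/29 % within a tenth of a point, the NPS peak
# does not move for pure amplitude scaling (levels 1-3), and only the
# calibrated level-4 blur shifts the peak (~ -6.7 %) while pulling the
# TTF landmarks down a few percent.

library(lungiq)

seed <- 101
dir.create("results", showWarnings = FALSE)

message("== phantom study, no extra blur ==")
res <- run_phantom_study(phantom_study_config(seed = seed))
print(res$noise_table, digits = 4)
print(res$ttf_table, digits = 4)
write.csv(res$noise_table, "results/phantom_noise_table.csv",
          row.names = FALSE)
write.csv(res$ttf_table, "results/phantom_ttf_table.csv",
          row.names = FALSE)
for (l in names(res$spectra))
  write_radial_spectrum(res$spectra[[l]],
                        sprintf("results/phantom_nps_level_%s.csv", l))

message("== calibrating level-4 blur for a -6.7% NPS peak shift ==")
cal <- calibrate_blur_for_peak_shift(target_shift_pct = -6.7,
                                     n_slices = 60, roi_size_px = 270,
                                     seed = seed + 1)
message(sprintf("calibrated blur sigma: %.3f mm (achieved %.2f%%)",
                cal$blur_sigma_mm, cal$achieved_shift_pct))

res4 <- run_phantom_study(phantom_study_config(
  seed = seed + 2,
  levels = recon_levels(extra_blur_sigma_mm = c(0, 0, 0, 0,
                                                cal$blur_sigma_mm))))
shift_tab <- data.frame(level = res4$noise_table$level,
                        nps_peak_shift_pct = res4$noise_table$peak_shift_pct,
                        ttf50_shift_pct = res4$ttf_table$ttf50_shift_pct,
                        ttf10_shift_pct = res4$ttf_table$ttf10_shift_pct)
print(shift_tab, digits = 3)
write.csv(shift_tab, "results/phantom_shift_table.csv", row.names = FALSE)
message("wrote results/phantom_*.csv")
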