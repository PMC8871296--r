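# lungiq

Quantitative image-quality assessment for chest CT, built for the
question every new reconstruction algorithm raises: *how much noise does
each strength level remove, and what does it cost in spatial
resolution?* The package implements the two standard measurement arms —
a phantom arm (noise power spectrum and target transfer function) and a
patient arm (automatic lung segmentation with global noise/SNR indices)
— together with a synthetic CT-volume generator that provides exact
ground truth (geometry, PSF, noise spectrum) for every stage, and the
agreement/multiplicity statistics used to analyze reader studies.

It is aimed at medical-physics and radiology researchers who want a
tested, scriptable pipeline for protocol or reconstruction comparisons,
and at method developers who need a controllable oracle to validate NPS
/ TTF / global-index estimators.

## The measurements

**Noise power spectrum (NPS).** From a stack of homogeneous ROIs (one
square ROI per slice, mean-subtracted, no trend removal):

    NPS(fx, fy) = (dx * dy / (Nx * Ny)) * < |DFT2{ROI - mean}|^2 >_slices

The angular mean in polar coordinates gives the 1D radial NPS; its
integral equals the noise variance (Parseval), so `sqrt(integral)` is
the noise magnitude in HU. The radial peak frequency (count-weighted
quadratic refinement of the spectral argmax) characterizes the noise
texture; peak shifts between reconstructions are reported in percent.

**Target transfer function (TTF).** A high-contrast cylindrical insert
(nominal 1050 HU vs water) is located with subvoxel precision; 72
radial edge spread functions are sampled every 5 degrees with a
10-degree aperture in 0.1-pixel radial bins, differentiated to line
spread functions, and Fourier-transformed:

    TTF(f) = |DFT{dESF/dr}| / |DFT{dESF/dr}|_{f=0}

TTF50 / TTF10 are the frequencies where modulation falls to 50% / 10%.
For a Gaussian PSF of width sigma, TTF(f) = exp(-2 pi^2 sigma^2 f^2)
and TTF50 = sqrt(ln 2 / 2 pi^2) / sigma — the closed forms the test
suite checks against.

**Global indices over the lungs.** The lungs are segmented by
thresholding (-400 HU), border-air removal, component selection,
closing and per-slice hole filling. Over the (eroded) mask, local mean
and SD maps on a 5x5 in-plane kernel give

    GNI   = mode of the histogram of local SD            [HU]
    GSNRI = mode of the histogram of |local mean| / local SD

plus the plain mean attenuation. Histogram modes use a fixed bin width
(1 HU / 0.1) with windowed quadratic refinement.

**Reader statistics.** Krippendorff's alpha (ordinal or nominal,
coincidence-matrix form with missing-data handling) and the
Benjamini–Hochberg step-up adjustment are implemented in the package;
Friedman / Wilcoxon / RM-ANOVA / paired-t orchestration delegates the
tests themselves to base R.

**Reconstruction emulation.** Strength levels are emulated in the image
domain as `blur(signal) + noise_scale * blur(noise)`: pure amplitude
scaling leaves the NPS shape untouched, while an optional small extra
blur (calibratable by bisection against a target peak shift) reproduces
the texture signature of aggressive iterative reconstruction.

## Worked example

```r
library(lungiq)

# a synthetic chest with known lung mask, plus stationary noise
chest <- make_chest_phantom(chest_spec(), shape = c(256, 256, 40),
                            spacing = c(1.4, 1.4, 2.5), psf_sigma_mm = 0.6,
                            noise = noise_model("white", 202, seed = 1))
mask  <- erode_for_metrics(segment_lungs(chest$volume), 2,
                           chest$volume$spacing)
stats <- local_stats(chest$volume, mask)
global_indices(chest$volume, mask, stats)
#> <global_index_result> GNI 199.1 HU, GSNRI 4.13, mean attenuation -843.0 HU (222375 voxels)
```

The GNI recovers the generated 202 HU noise within a few percent (the
small deficit is the sample-SD bias of the 5x5 kernel), the GSNRI
matches |−850|/202 ≈ 4.2, and the mean attenuation sits a few HU above
the −850 HU parenchyma because segmented lungs include ~1% vessel
voxels.

The full study drivers live in `analysis/`:

```sh
Rscript analysis/01_phantom_study.R    # NPS + TTF per level -> results/phantom_*.csv
Rscript analysis/02_cohort_study.R     # 10-case synthetic cohort -> results/cohort_*
Rscript analysis/03_reader_agreement.R # synthetic reader study -> results/reader_*
```

With its default seed, `01_phantom_study.R` prints measured
noise-magnitude fractions of exactly 100/78/59/43/29 % across levels
with peak shifts ~0, and a calibrated level-4 blur of 0.140 mm that
shifts the NPS peak by −6.7 %. `02_cohort_study.R` reports GNI falling
from ≈198 to ≈98 HU (−47.6 %) and GSNRI rising by ≈+90 %, with every
BH-adjusted pairwise comparison significant.

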