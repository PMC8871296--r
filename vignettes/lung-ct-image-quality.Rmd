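---
title: "Methods: phantom and in-vivo CT image-quality metrics in lungiq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom and in-vivo CT image-quality metrics in lungiq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungiq)
```

## Scope and model

`lungiq` measures how an image-domain change of reconstruction strength
affects CT image quality, in two arms:

* a **phantom arm**: the 2D noise power spectrum (NPS) of a homogeneous
  water region, reduced to a radial spectrum with noise magnitude, peak
  and mean frequency; and the target transfer function (TTF) of a
  high-contrast cylindrical insert, measured from angularly sectored
  radial edge spread functions (ESFs);
* a **patient arm**: automatic lung segmentation followed by voxelwise
  noise and SNR maps whose histogram modes are the Global Noise Index
  (GNI) and the Global SNR Index (GSNRI), plus the mean lung
  attenuation.

Because no scanner data ship with the package, a synthetic-data module
generates the inputs with exact ground truth. Reconstruction strength
is *emulated*, not modelled: each level multiplies a fixed noise
realization by a fraction and may add a small extra in-plane Gaussian
blur applied to signal and noise alike,

$$ I_\ell = G_{\sigma_\ell} * S + c_\ell \,(G_{\sigma_\ell} * N). $$

Amplitude scaling alone changes no spectral shape — exactly the
behaviour reported for moderate iterative strengths — while the extra
blur reproduces the peak-frequency shift seen only at the strongest
setting. The blur is applied to the noise as well as the signal
because a noise-spectrum shift is precisely the effect the emulation
must be able to produce; with zero extra blur the operation reduces to
plain `signal + scale * noise`.

Two level presets are provided. The default scales (1, 0.78, 0.59,
0.43, 0.29) are phantom noise-magnitude fractions; the patient preset
(1, 0.881, 0.762, 0.644, 0.525) carries the in-vivo lung GNI ratios of
a 202 HU baseline falling to 106 HU. They differ because measured
phantom noise and in-vivo organ noise need not fall at the same rate;
the cohort driver uses the patient preset so its GNI reduction
(≈ 47.5 %) is on the in-vivo scale.

## Synthetic data: what it emulates, and what it does not

`make_cylinder_phantom()` builds a water cylinder (default 25 cm, 0 HU)
with a coaxial insert (default 10 cm, 1050 HU — a PTFE-like
high-contrast rod); `make_chest_phantom()` builds an elliptic
soft-tissue body (40 HU) with two ellipsoidal lungs (−850 HU, the
attenuation scale of inspiratory parenchyma) and optional 2.5 mm
vessels (0 HU). Geometry is extruded along z and blurred in-plane by an
exact frequency-domain Gaussian PSF; noise is added afterwards.

Noise is stationary and slice-independent: white, or white filtered to
a prescribed radial power profile. The band-pass default
$P(f) \propto f\,e^{-f^2/2f_p^2}$ peaks exactly at $f_p$ (0.30 mm⁻¹ by
default) and stands in for the ramp-times-apodization texture of a
sharp reconstruction kernel; the true spectral shape of any particular
scanner kernel is deliberately not modelled, and the phantom arm's
conclusions are about the *estimators*, not about a device. Seeds are
mandatory arguments; generation never touches the global RNG stream.

Features of real data that the generator does **not** emulate — and
which passing tests therefore do not certify: non-stationary noise
(dose modulation, photon starvation), z-correlated noise, airways and
trachea, beam hardening and other artifacts, nonlinear
contrast-dependent resolution of iterative reconstruction, and real
lung texture. These are listed as limitations, not gaps the tests hide.

## Estimator choices

**NPS.** One ROI per slice (default 270 px at 0.586 mm pixels), mean
subtraction only — no polynomial detrend and no apodization window,
appropriate for a homogeneous phantom with no background gradient. The
2D periodogram is scaled by $dx\,dy/(N_x N_y)$ and averaged over
slices, so its integral is the noise variance; tests assert Parseval
against the directly computed ROI variance. Radial bins default to one
DFT frequency step; empty bins (sparse innermost rings) are linearly
interpolated. The mean frequency uses polar-measure weighting
($\sum f \cdot \mathrm{NPS}(f) f / \sum \mathrm{NPS}(f) f$), a choice
documented here because "average frequency" has no canonical
definition.

**Radial peak.** The radial NPS is flat near its peak relative to
per-bin estimator noise, so a raw argmax (or a 3-point parabola)
wanders by several bins — on a 270²-pixel, 60-slice stack the naive
estimator showed ±4 percentage-point jitter on a −6.7 % peak-shift
measurement. The package therefore refines the peak with a
count-weighted least-squares parabola on log-NPS over the bins within
±30 % of the peak frequency, which brought the same measurement to
−6.7 ± 0.3. The log transform makes band-pass spectra of the
ramp-times-Gaussian family near-quadratic across that window.

**TTF.** The insert is located by 3-centre intensity clustering, an
intensity-weighted centroid (subvoxel by symmetry) and the
half-contrast crossing of the mean radial profile. ESFs use the printed
sector scheme (72 sectors, 5° step, 10° aperture — adjacent sectors
share half their voxels) with 0.1-pixel radial bins over ±8 mm.
At that bin width the in-plane sample radii cannot cover every bin, so
empty bins are expected and interpolated; only a contiguous empty run
longer than 0.5 mm errors out, since there the ESF would be
unconstrained. A 3-bin moving average (configurable off) precedes the
central-difference derivative because differentiation amplifies bin
noise. The central difference has the exact transfer
$|\cos(\pi f \Delta r)|$ — the suite checks this in closed form on a
constructed ideal step — which is negligible over the usable band
(< 1.3 % below half the pixel Nyquist). No noise de-biasing of the TTF
is applied: at 1050 HU contrast the noise bias is negligible, and the
package does not claim validity for low-contrast TTF. Landmarks
(TTF50/TTF10) are first downward crossings with linear interpolation.
Supra-unity modulation after zero-frequency normalization is permitted
(edge-enhancing kernels can produce it) but nothing is asserted about
it.

**Segmentation.** Threshold −400 HU (midway between −850 HU parenchyma
and +40 HU soft tissue), removal of border-connected air, at most the
two largest 26-connected components ≥ 200 ml, ball closing (2 mm) and
per-slice hole filling (3D filling would seal the mediastinum). A
one-voxel despeckle opening precedes component analysis: at ~200 HU
noise a few percent of soft-tissue voxels fall below the threshold, and
under 26-connectivity that speckle percolates, spuriously connecting
the lungs to outside air. Metrics always use a mask eroded by 2 mm so
local kernels sit inside parenchyma. No airway/trachea removal is
implemented (the phantoms have none); on real data this is a known
limitation. Morphology uses an exact anisotropic Euclidean distance
transform, so radii are physical and spacing-aware.

**Global indices.** Local statistics use a 5×5 in-plane kernel
truncated at the mask boundary (no padding, so edge HU never leaks in)
with at least 15 contributing voxels. SNR is $|\text{local mean}| /
\text{local SD}$: lung attenuation is negative while the index is
conventionally positive ($850/202 \approx 4.2$). Histogram bins are
1 HU (noise) and 0.1 (SNR). The histogram mode uses the same windowed
quadratic refinement as the spectral peak (window ≈ a quarter of the
robust SD): with a broad unimodal histogram the maximal bin alone is
noise-dominated, and the windowed fit reduced the mode estimator's SD
from > 1 HU to < 0.3 HU on a 10⁶-sample Gaussian test. The GNI of the
5×5 kernel carries the small-sample SD bias (mode of
$\sigma\sqrt{\chi^2_{24}/24}$, ≈ −2 %); it is reported as measured,
not corrected, matching how such indices are used in practice.

**Statistics.** Krippendorff's alpha uses the ordinal metric by
default (5-point Likert data; nominal available), in the
coincidence-matrix formulation with pairable-value handling of missing
scores. Benjamini–Hochberg is the exact step-up rule (`min` over the
rank tail of $m p_{(j)}/j$, capped at 1). Both are implemented in the
package and tested against brute-force computations and `p.adjust`;
the omnibus and pairwise tests (Friedman/Wilcoxon, RM-ANOVA/paired t)
are delegated to `stats`. The conventional alpha interpretation bands
(≤ 0.20 poor … > 0.80 almost perfect) are attached to the estimate.
Note that BH is *not* idempotent — re-adjusting adjusted values can
increase them — so the suite asserts monotonicity and the oracle match
instead.

## Numerical and degenerate-input behaviour

* All geometry must fit the field of view; the ESF window must stay
  inside the water annulus (insert radius + window + |offset| < phantom
  radius), which the fixtures respect by construction.
* Histogram-mode ties break toward the lower bin; a single-valued input
  returns that value exactly.
* A noise-free volume makes every local SD zero, so all SNR values are
  undefined and `global_indices()` errors rather than returning an
  infinite index.
* Erosion larger than the structure returns an empty mask with a
  warning; zero radii are identities.
* `emulate_reconstruction()` at level `off` is the bitwise identity on
  `signal + noise`.

## Problem sizes

The shipped drivers and tests run at desk scale, chosen so every
estimator operates in its asymptotic regime: NPS stacks of 40–100
slices at 128–270 px; TTF grids of 384² at 0.2 mm with 1–6 slices;
chests of 192²×32 to 256²×52 voxels; cohorts of 3–10 cases. The
estimators themselves are size-agnostic, and the NPS/TTF arms match
the printed acquisition geometry (270-px ROI, 72 sectors) exactly.

## Known limitations

* The reconstruction emulation is an image-domain stand-in; it cannot
  reproduce nonlinear, contrast- and dose-dependent behaviour of real
  iterative algorithms.
* GNI/GSNRI inherit kernel-size and bin-width conventions; absolute
  values are comparable only within a fixed configuration.
* In the emulation, GSNRI scales almost exactly as the reciprocal of
  the noise scale (a 0.525 noise fraction yields ≈ +90 % GSNRI); in
  patients the two histogram modes need not be exact reciprocals, so
  in-vivo GSNRI changes can differ from the reciprocal rule.
* Segmentation is threshold/region-based and vessel-inclusive after
  closing and hole filling (~1 % of lung voxels at 0 HU raise mean
  attenuation by ≈ 6 HU); atlas- or learning-based methods and airway
  removal are out of scope.
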