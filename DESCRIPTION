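Package: lungiq
Title: Quantitative Image Quality Metrics for Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phantom- and patient-domain image quality assessment for
    computed tomography of the lung. Implements noise power spectrum (NPS)
    estimation from homogeneous phantom regions with radial reduction and
    peak/mean-frequency summaries, target transfer function (TTF)
    measurement from angularly sectored radial edge spread functions of a
    high-contrast cylindrical insert, automatic threshold- and region-based
    lung segmentation, voxelwise noise and signal-to-noise-ratio maps with
    histogram-mode reduction to the Global Noise Index (GNI) and Global SNR
    Index (GSNRI), inter-reader agreement via Krippendorff's alpha and
    Benjamini-Hochberg multiplicity correction, and a synthetic CT-volume
    generator with known geometry, point spread function and noise spectrum
    that serves as ground truth for every stage, including an image-domain
    emulation of iterative-reconstruction strength levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
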