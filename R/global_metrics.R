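#' Local mean and noise (SD) maps over a mask
#'
#' For every mask voxel, the mean and sample standard deviation of the HU
#' values in the in-plane square kernel of half-width `kernel_radius_vox`
#' (default 2, i.e. 5 x 5) intersected with the mask. Kernels are
#' truncated at the mask boundary rather than padded, so edge HU never
#' contaminates the statistics; voxels with fewer than `min_kernel_count`
#' in-mask neighbours are left undefined (NA).
#'
#' @param volume an [image_volume].
#' @param mask logical array of the target region (e.g. eroded lungs).
#' @param kernel_radius_vox kernel half-width in voxels (>= 1).
#' @param min_kernel_count minimum in-mask kernel voxels for a defined
#'   value.
#' @return A `local_stats_map`: `local_mean_hu`, `local_sd_hu` (arrays,
#'   NA off-mask/undefined), `kernel_radius_vox`, `min_kernel_count`,
#'   `n_defined`.
#' @export
local_stats <- function(volume, mask, kernel_radius_vox = 2,
                        min_kernel_count = 15) {
  stopifnot_volume(volume)
  if (!any(mask)) stop("mask is empty")
  if (!identical(dim(volume$voxels), dim(mask)))
    stop("mask must match the volume shape")
  max_n <- (2 * kernel_radius_vox + 1)^2
  if (kernel_radius_vox < 1 || max_n < min_kernel_count)
    stop("kernel too small to ever reach `min_kernel_count` voxels")
  st <- .local_stats(volume$voxels, mask, as.integer(kernel_radius_vox),
                     as.integer(min_kernel_count))
  structure(list(local_mean_hu = st$mean, local_sd_hu = st$sd,
                 kernel_radius_vox = kernel_radius_vox,
                 min_kernel_count = min_kernel_count,
                 n_defined = sum(!is.na(st$sd))),
            class = "local_stats_map")
}

#' Mode of a histogram with quadratic refinement
#'
#' Bins the values with a fixed bin width, takes the maximal bin (ties
#' broken toward the lower bin) and refines the mode by a quadratic fit
#' to the neighbouring bin counts: a least-squares parabola over the
#' bins within a window scaled to the histogram's spread (a quarter of
#' the robust SD, at least one bin on each side). When the window is the
#' minimal one this reduces to the classic 3-point interpolation; the
#' wider stencil is what makes the vertex stable when the peak is broad
#' relative to the bin width, where the raw argmax (and a 3-point fit)
#' wander by several bins from count noise alone.
#'
#' @param values numeric vector (NAs dropped). Fewer than 1000 values
#'   triggers a warning: the mode of a sparse histogram is unstable.
#' @param bin_width histogram bin width, > 0.
#' @return the mode (scalar).
#' @export
histogram_mode <- function(values, bin_width) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values")
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  if (length(values) < 1000)
    warning("fewer than 1000 values: histogram mode may be unstable")
  if (max(values) == min(values)) return(values[1])
  h <- hist_fixed(values, bin_width)
  nb <- length(h$counts)
  spread <- stats::IQR(values) / 1.349   # robust SD
  w <- max(1L, min(as.integer(round(0.25 * spread / bin_width)),
                   (nb - 1L) %/% 2L))
  # locate the peak on counts smoothed at the window scale, so the fit
  # window is centred on the true peak rather than a noise spike
  sm <- if (w > 1) stats::filter(h$counts, rep(1 / (2 * w + 1), 2 * w + 1),
                                 sides = 2) else h$counts
  sm[is.na(sm)] <- -Inf
  i <- which.max(sm)   # which.max takes the first (lower) tie
  lo <- max(1L, i - w); hi <- min(nb, i + w)
  if (hi - lo < 2L) return(h$centers[i])
  x <- h$centers[lo:hi] - h$centers[i]
  y <- h$counts[lo:hi]
  fit <- stats::lm.fit(cbind(1, x, x^2), y)
  a2 <- fit$coefficients[3]; a1 <- fit$coefficients[2]
  if (!is.finite(a2) || a2 >= 0) return(h$centers[i])
  vertex <- -a1 / (2 * a2)
  # keep the refinement local: never move beyond the fit window
  vertex <- max(min(vertex, x[length(x)]), x[1])
  h$centers[i] + vertex
}

hist_fixed <- function(values, bin_width) {
  lo <- floor(min(values) / bin_width) * bin_width
  n <- max(1L, ceiling((max(values) - lo) / bin_width + 1e-9))
  idx <- pmin(pmax(floor((values - lo) / bin_width) + 1L, 1L), n)
  counts <- tabulate(idx, nbins = n)
  list(edges = lo + (0:n) * bin_width,
       centers = lo + (seq_len(n) - 0.5) * bin_width,
       counts = counts)
}

#' Global noise and SNR indices over a segmented region
#'
#' The Global Noise Index (GNI) is the histogram mode of the local-SD
#' (noise) map over the region; the SNR map divides the magnitude of the
#' local mean attenuation by the local SD, and its histogram mode is the
#' Global SNR Index (GSNRI). Lung attenuation is negative while the
#' reported index is positive, hence the magnitude. Mean attenuation is
#' the plain mean HU of the original volume over all mask voxels,
#' independent of any kernel parameter.
#'
#' @param volume the [image_volume] the stats were computed from.
#' @param mask the mask the stats were computed over.
#' @param stats a [local_stats()] map.
#' @param noise_bin_hu noise-histogram bin width (HU).
#' @param snr_bin SNR-histogram bin width.
#' @return A `global_index_result`: `gni_hu`, `gsnri`,
#'   `mean_attenuation_hu`, `noise_histogram`, `snr_histogram`,
#'   `n_voxels` (defined noise-map voxels), `n_snr_excluded` (local SD
#'   exactly 0).
#' @export
global_indices <- function(volume, mask, stats, noise_bin_hu = 1.0,
                           snr_bin = 0.1) {
  stopifnot_volume(volume)
  if (!inherits(stats, "local_stats_map"))
    stop("`stats` must come from local_stats()")
  sd_vals <- stats$local_sd_hu[!is.na(stats$local_sd_hu)]
  if (length(sd_vals) == 0) stop("no defined noise-map voxels")
  defined <- !is.na(stats$local_sd_hu)
  nonzero <- defined & stats$local_sd_hu > 0
  n_excluded <- sum(defined) - sum(nonzero)
  if (!any(nonzero)) stop("all SNR values undefined (local SD is zero)")
  snr_vals <- abs(stats$local_mean_hu[nonzero]) / stats$local_sd_hu[nonzero]
  gni <- histogram_mode(sd_vals, noise_bin_hu)
  gsnri <- histogram_mode(snr_vals, snr_bin)
  structure(list(gni_hu = gni, gsnri = gsnri,
                 mean_attenuation_hu = mean(volume$voxels[mask]),
                 noise_histogram = hist_fixed(sd_vals, noise_bin_hu),
                 snr_histogram = hist_fixed(snr_vals, snr_bin),
                 n_voxels = length(sd_vals),
                 n_snr_excluded = n_excluded),
            class = "global_index_result")
}

#' @export
print.global_index_result <- function(x, ...) {
  cat(sprintf("<global_index_result> GNI %.1f HU, GSNRI %.2f, mean attenuation %.1f HU (%d voxels)\n",
              x$gni_hu, x$gsnri, x$mean_attenuation_hu, x$n_voxels))
  invisible(x)
}

#' Summarize global indices across reconstruction levels
#'
#' Takes a long table of per-case, per-level results and reports, per
#' level: mean and SD of GNI, GSNRI and mean attenuation across cases,
#' percent change of GNI and GSNRI relative to the first (reference)
#' level, and monotonicity flags for the level-ordered means.
#'
#' @param results data frame with columns `case`, `level`, `gni_hu`,
#'   `gsnri`, `mean_attenuation_hu`; every level must cover the same
#'   cases. `level` order follows first appearance.
#' @return data frame, one row per level, with attributes
#'   `gni_monotone_decreasing` and `gsnri_monotone_increasing`.
#' @export
compare_reconstructions <- function(results) {
  need <- c("case", "level", "gni_hu", "gsnri", "mean_attenuation_hu")
  if (!all(need %in% names(results))) stop("missing columns")
  levels_seen <- unique(results$level)
  if (length(levels_seen) < 2) stop("need >= 2 levels")
  case_sets <- split(results$case, results$level)
  ref_cases <- sort(unique(results$case))
  for (cs in case_sets)
    if (!identical(sort(unique(cs)), ref_cases))
      stop("levels cover different case sets")
  agg <- function(col, f) vapply(levels_seen, function(l)
    f(results[[col]][results$level == l]), numeric(1))
  out <- data.frame(level = levels_seen,
                    gni_mean = agg("gni_hu", mean),
                    gni_sd = agg("gni_hu", stats::sd),
                    gsnri_mean = agg("gsnri", mean),
                    gsnri_sd = agg("gsnri", stats::sd),
                    mean_attenuation_mean = agg("mean_attenuation_hu", mean),
                    mean_attenuation_sd = agg("mean_attenuation_hu", stats::sd),
                    stringsAsFactors = FALSE)
  out$gni_change_pct <- 100 * (out$gni_mean / out$gni_mean[1] - 1)
  out$gsnri_change_pct <- 100 * (out$gsnri_mean / out$gsnri_mean[1] - 1)
  attr(out, "gni_monotone_decreasing") <- all(diff(out$gni_mean) < 0)
  attr(out, "gsnri_monotone_increasing") <- all(diff(out$gsnri_mean) > 0)
  out
}
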