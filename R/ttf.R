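#' Locate a high-contrast cylindrical insert
#'
#' Finds the insert axis and edge radius with subvoxel precision from the
#' slice-averaged image: intensities are clustered (3-centre 1D k-means) to
#' separate the insert from its background, the centre is the
#' intensity-weighted centroid of the largest thresholded component, and
#' the radius is the half-contrast crossing of the mean radial profile.
#'
#' @param volume an [image_volume] containing the insert.
#' @param slice_range slice indices to average; default all.
#' @param min_contrast_hu minimum insert/background contrast; below this
#'   the search fails.
#' @return list with `center_xy_mm` (relative to the slice centre),
#'   `radius_mm`, `inner_hu`, `outer_hu`.
#' @export
fit_insert_edge <- function(volume, slice_range = NULL,
                            min_contrast_hu = 100) {
  stopifnot_volume(volume)
  d <- dim(volume$voxels)
  if (is.null(slice_range)) slice_range <- seq_len(d[3])
  m <- apply(volume$voxels[, , slice_range, drop = FALSE], c(1, 2), mean)
  centers0 <- stats::quantile(m, c(0.1, 0.5, 0.98))
  if (max(centers0) - min(centers0) < min_contrast_hu)
    stop("no high-contrast insert found")
  km <- stats::kmeans(as.vector(m), centers = unique(as.numeric(centers0)))
  cl <- sort(km$centers[, 1], decreasing = TRUE)
  if (cl[1] - cl[2] < min_contrast_hu)
    stop("no high-contrast insert found")
  thr <- (cl[1] + cl[2]) / 2
  bin <- m >= thr
  lab <- .cc_label(array(bin, dim = c(d[1], d[2], 1L)), 26L)[, , 1]
  sizes <- tabulate(lab)
  if (length(sizes) == 0) stop("no high-contrast insert found")
  comp <- lab == which.max(sizes)
  g <- plane_coords(d[1], d[2], volume$spacing)
  w <- (m - thr) * comp
  w[w < 0] <- 0
  cx <- sum(w * g$x) / sum(w)
  cy <- sum(w * g$y) / sum(w)
  # radius from the half-contrast crossing of the mean radial profile
  r <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  dx <- volume$spacing[1]
  r0 <- sqrt(sum(comp) * dx * volume$spacing[2] / pi)
  inner <- mean(m[r < 0.7 * r0])
  out_lo <- r0 + 2 * dx
  out_hi <- min(r0 + 8 * dx, max(r) * 0.95)
  outer <- mean(m[r > out_lo & r < out_hi])
  half <- (inner + outer) / 2
  bw <- 0.2 * dx
  sel <- r < out_hi
  bi <- floor(r[sel] / bw) + 1L
  prof <- tapply(m[sel], bi, mean)
  pr <- as.numeric(prof)
  pf <- (as.integer(names(prof)) - 0.5) * bw
  below <- which(pr < half & pf > 0.5 * r0)
  if (length(below) == 0 || below[1] < 2) stop("no edge crossing found")
  i <- below[1]
  radius <- pf[i - 1] + (pr[i - 1] - half) / (pr[i - 1] - pr[i]) *
    (pf[i] - pf[i - 1])
  list(center_xy_mm = c(cx, cy), radius_mm = radius,
       inner_hu = inner, outer_hu = outer)
}

#' Radial edge spread functions in angular sectors
#'
#' Samples every voxel within `window_mm` of the fitted edge radius into
#' angular sectors placed every `sector_step_deg` degrees with an
#' `aperture_deg`-wide aperture (with the default 5-degree step and
#' 10-degree aperture, adjacent sectors overlap and share half their
#' voxels). Each sector's samples are pooled over slices and averaged in
#' uniform subpixel radial bins, yielding one oversampled ESF per sector
#' as a function of signed distance from the edge (negative = inside the
#' insert).
#'
#' @param volume an [image_volume].
#' @param center in-plane centre (x, y) in mm relative to the slice
#'   centre, as returned by [fit_insert_edge()].
#' @param radius edge radius in mm.
#' @param n_sectors number of sectors (default 72).
#' @param sector_step_deg angular step between sector centres.
#' @param aperture_deg full angular aperture of each sector.
#' @param bin_width_px radial bin width in pixels (default 0.1).
#' @param window_mm half-width of the radial window around the edge.
#' @param slice_range slices to pool; default all.
#' @param max_gap_mm interpolation tolerance: empty bins are filled by
#'   linear interpolation, but a contiguous run of empty bins longer
#'   than this is an error (the ESF would be unconstrained there).
#'   Individual empty bins are expected: at 0.1-pixel resolution the
#'   in-plane sample radii do not cover every bin.
#' @return list of `esf_profile` objects (`positions`, `hu`,
#'   `sector_angle_deg`, `n_samples`, `bin_width_mm`).
#' @export
extract_radial_esf <- function(volume, center, radius, n_sectors = 72,
                               sector_step_deg = 5, aperture_deg = 10,
                               bin_width_px = 0.1, window_mm = 8,
                               slice_range = NULL, max_gap_mm = 0.5) {
  stopifnot_volume(volume)
  if (n_sectors * sector_step_deg < 360)
    stop("sectors must cover 360 degrees")
  d <- dim(volume$voxels)
  if (is.null(slice_range)) slice_range <- seq_len(d[3])
  g <- plane_coords(d[1], d[2], volume$spacing)
  rx <- g$x - center[1]
  ry <- g$y - center[2]
  r <- sqrt(rx^2 + ry^2)
  theta <- (atan2(ry, rx) * 180 / pi) %% 360
  annulus <- abs(r - radius) <= window_mm
  bw <- bin_width_px * volume$spacing[1]
  breaks <- seq(-window_mm, window_mm, by = bw)
  centers <- breaks[-1] - bw / 2
  nb <- length(centers)
  nxy <- d[1] * d[2]
  slice_off <- (slice_range - 1L) * nxy
  profiles <- vector("list", n_sectors)
  for (k in seq_len(n_sectors)) {
    ang <- (k - 1) * sector_step_deg
    angdiff <- ((theta - ang + 180) %% 360) - 180
    sel <- annulus & abs(angdiff) <= aperture_deg / 2
    idx2 <- which(sel)
    pos <- r[idx2] - radius
    bi <- pmin(pmax(floor((pos + window_mm) / bw) + 1L, 1L), nb)
    vals <- as.numeric(volume$voxels[rep(idx2, length(slice_off)) +
                                     rep(slice_off, each = length(idx2))])
    bi_all <- rep(bi, length(slice_off))
    sums <- tapply(vals, bi_all, sum)
    cnts <- tapply(vals, bi_all, length)
    hu <- rep(NA_real_, nb)
    n_samp <- integer(nb)
    ii <- as.integer(names(sums))
    hu[ii] <- sums / cnts
    n_samp[ii] <- cnts
    empty <- is.na(hu)
    if (any(empty)) {
      runs <- rle(empty)
      if (max(runs$lengths[runs$values]) * bw > max_gap_mm)
        stop(sprintf("sector %d: empty radial gap exceeds %.2f mm", k - 1,
                     max_gap_mm))
    }
    if (any(empty)) {
      hu[empty] <- stats::approx(centers[!empty], hu[!empty],
                                 xout = centers[empty], rule = 2)$y
    }
    profiles[[k]] <- structure(list(positions = centers, hu = hu,
                                    sector_angle_deg = ang,
                                    n_samples = n_samp,
                                    bin_width_mm = bw),
                               class = "esf_profile")
  }
  profiles
}

#' Target transfer function from an edge spread function
#'
#' Differentiates the binned ESF (after an optional 3-bin moving-average
#' smoothing; the derivative amplifies bin noise) by central differences
#' to obtain the line spread function, takes the modulus of its
#' zero-padded discrete Fourier transform, and normalizes by the
#' zero-frequency value so modulation(0) = 1. The contrast is the
#' difference of the two end plateaus.
#'
#' @param esf an `esf_profile`.
#' @param smooth apply 3-bin moving-average smoothing (default TRUE).
#' @param pad_factor zero-padding factor for the DFT (finer frequency
#'   sampling of a smooth curve).
#' @return A `ttf_curve`: `frequencies` (1/mm, up to Nyquist of the bin
#'   pitch), `modulation`, `ttf50`, `ttf10`, `contrast_hu`.
#' @export
esf_to_ttf <- function(esf, smooth = TRUE, pad_factor = 4) {
  if (!inherits(esf, "esf_profile")) stop("`esf` must be an esf_profile")
  hu <- esf$hu
  n <- length(hu)
  if (smooth) {
    sm <- stats::filter(hu, rep(1 / 3, 3), sides = 2)
    hu[2:(n - 1)] <- sm[2:(n - 1)]
  }
  np <- max(3L, round(0.1 * n))
  plateau_in <- mean(hu[seq_len(np)])        # negative positions = inside
  plateau_out <- mean(hu[(n - np + 1):n])
  contrast <- plateau_in - plateau_out
  if (contrast <= 0) stop("non-positive edge contrast")
  dr <- esf$bin_width_mm
  lsf <- numeric(n)
  lsf[2:(n - 1)] <- (hu[3:n] - hu[1:(n - 2)]) / (2 * dr)
  lsf[1] <- (hu[2] - hu[1]) / dr
  lsf[n] <- (hu[n] - hu[n - 1]) / dr
  npad <- pad_factor * n
  mod_full <- Mod(stats::fft(c(lsf, numeric(npad - n))))
  freqs <- (seq_len(npad) - 1) / (npad * dr)
  keep <- freqs <= 1 / (2 * dr)
  modv <- mod_full[keep] / mod_full[1]
  new_ttf_curve(freqs[keep], modv, contrast)
}

new_ttf_curve <- function(frequencies, modulation, contrast) {
  structure(list(frequencies = frequencies, modulation = modulation,
                 ttf50 = ttf_landmark(frequencies, modulation, 0.5),
                 ttf10 = ttf_landmark(frequencies, modulation, 0.1),
                 contrast_hu = contrast),
            class = "ttf_curve")
}

# first downward crossing of `thr`, linearly interpolated
ttf_landmark <- function(freq, modulation, thr) {
  below <- which(modulation < thr)
  if (length(below) == 0 || below[1] == 1L)
    stop(sprintf("curve never crosses %.2f within Nyquist", thr))
  i <- below[1]
  freq[i - 1] + (modulation[i - 1] - thr) /
    (modulation[i - 1] - modulation[i]) * (freq[i] - freq[i - 1])
}

#' Average TTF curves over angular sectors
#'
#' Pointwise mean of the modulation values of curves sharing one frequency
#' grid; the TTF50/TTF10 landmarks are recomputed on the averaged curve.
#'
#' @param curves list of `ttf_curve` objects on identical grids.
#' @return A `ttf_curve`.
#' @export
average_ttf <- function(curves) {
  if (length(curves) == 0) stop("no curves to average")
  f0 <- curves[[1]]$frequencies
  for (cv in curves) {
    if (!inherits(cv, "ttf_curve")) stop("all elements must be ttf_curve")
    if (length(cv$frequencies) != length(f0) ||
        max(abs(cv$frequencies - f0)) > 1e-9)
      stop("curves are not on the same frequency grid")
  }
  m <- rowMeans(vapply(curves, function(cv) cv$modulation,
                       numeric(length(f0))))
  contrast <- mean(vapply(curves, function(cv) cv$contrast_hu, numeric(1)))
  new_ttf_curve(f0, m, contrast)
}

#' TTF landmark shifts between two reconstructions
#'
#' Percent change of the TTF50 and TTF10 frequencies of a test curve
#' relative to a reference: `100 * (f_test - f_ref) / f_ref`.
#'
#' @param test,reference `ttf_curve` objects.
#' @return named numeric `c(ttf50_shift_pct, ttf10_shift_pct)`.
#' @export
ttf_landmarks_and_shift <- function(test, reference) {
  if (!inherits(test, "ttf_curve") || !inherits(reference, "ttf_curve"))
    stop("inputs must be ttf_curve objects")
  c(ttf50_shift_pct = 100 * (test$ttf50 - reference$ttf50) / reference$ttf50,
    ttf10_shift_pct = 100 * (test$ttf10 - reference$ttf10) / reference$ttf10)
}

#' Measure the averaged TTF of an insert in one call
#'
#' Convenience wrapper: [fit_insert_edge()], [extract_radial_esf()],
#' [esf_to_ttf()] per sector, [average_ttf()].
#'
#' @inheritParams extract_radial_esf
#' @param ... passed to [extract_radial_esf()].
#' @param smooth,pad_factor passed to [esf_to_ttf()].
#' @return A `ttf_curve`.
#' @export
measure_ttf <- function(volume, slice_range = NULL, smooth = TRUE,
                        pad_factor = 4, ...) {
  fit <- fit_insert_edge(volume, slice_range = slice_range)
  esfs <- extract_radial_esf(volume, fit$center_xy_mm, fit$radius_mm,
                             slice_range = slice_range, ...)
  average_ttf(lapply(esfs, esf_to_ttf, smooth = smooth,
                     pad_factor = pad_factor))
}
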