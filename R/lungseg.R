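#' Lung segmentation parameters
#'
#' @param air_threshold_hu voxels below this HU are candidate air/lung
#'   (default -400, midway between lung parenchyma near -850 HU and soft
#'   tissue near +40 HU).
#' @param min_component_ml minimum connected-component volume kept (ml).
#' @param opening_radius_mm despeckle opening applied to the raw air mask
#'   before connected-component analysis. At high noise a few percent of
#'   soft-tissue voxels fall below the air threshold and such speckle
#'   percolates under 26-connectivity, spuriously bridging the lungs to
#'   the outside air; a one-voxel opening removes it. The default `NA`
#'   resolves to the in-plane voxel pitch at segmentation time.
#' @param closing_radius_mm morphological closing radius that
#'   reincorporates small intrapulmonary vessels (mm).
#' @param border_margin_vox voxels stripped from the volume border of the
#'   final mask.
#' @param boundary_erosion_mm default erosion applied before metric
#'   computation (see [erode_for_metrics()]).
#' @return A `seg_params` list.
#' @export
seg_params <- function(air_threshold_hu = -400, min_component_ml = 200,
                       opening_radius_mm = NA, closing_radius_mm = 2,
                       border_margin_vox = 1, boundary_erosion_mm = 2) {
  if (air_threshold_hu >= 0) stop("`air_threshold_hu` must be negative")
  if (closing_radius_mm < 0 || boundary_erosion_mm < 0 ||
      (!is.na(opening_radius_mm) && opening_radius_mm < 0) ||
      min_component_ml < 0)
    stop("radii and volumes must be >= 0")
  structure(list(air_threshold_hu = air_threshold_hu,
                 min_component_ml = min_component_ml,
                 opening_radius_mm = opening_radius_mm,
                 closing_radius_mm = closing_radius_mm,
                 border_margin_vox = border_margin_vox,
                 boundary_erosion_mm = boundary_erosion_mm),
            class = "seg_params")
}

#' Automatic lung segmentation
#'
#' Threshold- and region-based extraction of the lungs from a chest CT
#' volume: (1) binarize voxels below `air_threshold_hu`; (2) discard air
#' connected to the volume border (the surrounding atmosphere); (3) keep
#' the up-to-two largest 26-connected components of at least
#' `min_component_ml`; (4) morphological closing with a physical-radius
#' ball (`closing_radius_mm`) to reincorporate small vessels; (5) fill 2D
#' holes slice by slice (per-slice filling avoids sealing the
#' mediastinum); finally strip `border_margin_vox` voxels at the volume
#' border. Deterministic; no airway-tree removal (a limitation on real
#' data with a visible trachea).
#'
#' @param volume an [image_volume] in HU.
#' @param params a [seg_params()].
#' @return logical 3D array (the lung mask) with attributes
#'   `voxel_count` and `volume_ml`.
#' @export
segment_lungs <- function(volume, params = seg_params()) {
  stopifnot_volume(volume)
  d <- dim(volume$voxels)
  air <- volume$voxels < params$air_threshold_hu
  if (!any(air)) stop("no lungs found")
  open_r <- params$opening_radius_mm
  if (is.na(open_r)) open_r <- max(volume$spacing[1:2])
  if (open_r > 0) {
    air <- erode_ball_interior(air, open_r, volume$spacing)
    air <- dilate_ball(air, open_r, volume$spacing)
    if (!any(air)) stop("no lungs found")
  }
  lab <- .cc_label(air, 26L)
  border_labels <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                            lab[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0]
  sizes <- tabulate(lab)
  voxel_ml <- prod(volume$spacing) / 1000
  keep_labels <- setdiff(which(sizes * voxel_ml >= params$min_component_ml),
                         border_labels)
  if (length(keep_labels) == 0) stop("no lungs found")
  if (length(keep_labels) > 2)
    keep_labels <- keep_labels[order(sizes[keep_labels],
                                     decreasing = TRUE)][1:2]
  mask <- array(lab %in% keep_labels, dim = d)
  if (params$closing_radius_mm > 0) {
    mask <- dilate_ball(mask, params$closing_radius_mm, volume$spacing)
    mask <- erode_ball(mask, params$closing_radius_mm, volume$spacing)
  }
  mask <- fill_holes_slicewise(mask)
  bm <- params$border_margin_vox
  if (bm > 0) {
    mask[c(seq_len(bm), d[1] - seq_len(bm) + 1), , ] <- FALSE
    mask[, c(seq_len(bm), d[2] - seq_len(bm) + 1), ] <- FALSE
    mask[, , c(seq_len(bm), d[3] - seq_len(bm) + 1)] <- FALSE
  }
  as_voxel_mask(mask, volume$spacing)
}

as_voxel_mask <- function(mask, spacing) {
  structure(mask, voxel_count = sum(mask),
            volume_ml = sum(mask) * prod(spacing) / 1000)
}

#' Erode a mask for metric computation
#'
#' Morphological erosion by a ball of physical radius `erosion_mm`, used
#' so local-statistics kernels sit fully inside parenchyma and boundary
#' voxels (partial-volume HU) do not bias noise maps. An empty result is
#' allowed but triggers a warning.
#'
#' @param mask logical 3D array.
#' @param erosion_mm erosion radius in mm (0 = identity).
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @return eroded logical array with `voxel_count`/`volume_ml` attributes.
#' @export
erode_for_metrics <- function(mask, erosion_mm, spacing) {
  if (erosion_mm < 0) stop("`erosion_mm` must be >= 0")
  if (erosion_mm == 0) return(as_voxel_mask(mask, spacing))
  out <- erode_ball(mask, erosion_mm, spacing)
  if (!any(out)) warning("erosion produced an empty mask")
  as_voxel_mask(out, spacing)
}

# ball morphology via the anisotropic Euclidean distance transform:
# erosion keeps voxels farther than r from the background, dilation adds
# voxels within r of the foreground. Outside the volume counts as
# background.
erode_ball <- function(mask, radius_mm, spacing) {
  dist2 <- .edt_sq(!mask, as.numeric(spacing))
  out <- array(dist2 > radius_mm^2, dim = dim(mask))
  # outside the volume is background: strip voxels too close to the border
  out & !border_shell(dim(mask), spacing, radius_mm)
}

# erosion treating the outside of the volume as foreground (used for the
# despeckle opening of the air mask: air beyond the FOV is still air)
erode_ball_interior <- function(mask, radius_mm, spacing) {
  dist2 <- .edt_sq(!mask, as.numeric(spacing))
  array(dist2 > radius_mm^2, dim = dim(mask))
}

dilate_ball <- function(mask, radius_mm, spacing) {
  dist2 <- .edt_sq(mask, as.numeric(spacing))
  array(dist2 <= radius_mm^2, dim = dim(mask))
}

border_shell <- function(d, spacing, radius_mm) {
  sh <- array(FALSE, dim = d)
  n <- pmin(ceiling(radius_mm / spacing), d)
  for (ax in 1:3) {
    if (n[ax] < 1) next
    idx <- c(seq_len(n[ax]), d[ax] - seq_len(n[ax]) + 1)
    if (ax == 1) sh[idx, , ] <- TRUE
    else if (ax == 2) sh[, idx, ] <- TRUE
    else sh[, , idx] <- TRUE
  }
  sh
}

# fill 2D holes per slice: background connected to the slice border stays
# background, any other non-mask pixel becomes mask
fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    bg <- array(!sl, dim = c(d[1], d[2], 1L))
    lab <- .cc_label(bg, 6L)[, , 1]
    border_labs <- unique(c(lab[c(1, d[1]), ], lab[, c(1, d[2])]))
    border_labs <- border_labs[border_labs > 0]
    hole <- !sl & !(lab %in% border_labs)
    mask[, , k] <- sl | hole
  }
  mask
}

#' Dice overlap coefficient
#'
#' `2|A & B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @param a,b logical arrays of identical shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share shape")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
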