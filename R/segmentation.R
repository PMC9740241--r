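ball_offsets <- function(radius_mm, spacing_mm) {
  r <- pmax(0L, as.integer(floor(radius_mm / spacing_mm)))
  g <- expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3])
  keep <- (g$i * spacing_mm[1])^2 + (g$j * spacing_mm[2])^2 +
    (g$k * spacing_mm[3])^2 <= radius_mm^2
  m <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

binary_close <- function(mask, radius_mm, spacing_mm) {
  off <- ball_offsets(radius_mm, spacing_mm)
  if (nrow(off) <= 1) return(mask)
  morph_cpp(morph_cpp(mask, off, grow = TRUE), off, grow = FALSE)
}

#' Segment the femur from a calibrated volume
#'
#' Classical stand-in for a learned segmentation model: density threshold,
#' largest 26-connected component, morphological closing and interior hole
#' fill.  Lytic lesions fall below the threshold but are recovered by the
#' hole fill, so the mask is the full bone envelope.  Components overlapping
#' declared phantom-rod regions are discarded before picking the largest one.
#'
#' @param volume a calibrated [bos_volume] (mg/cm^3).
#' @param density_threshold_mg_cm3 bone threshold (default 150 mg/cm^3,
#'   between soft tissue/marrow and trabecular bone in the synthetic model).
#' @param closing_radius_mm closing ball radius (default 2 mm).
#' @param rod_masks optional list of logical arrays flagging phantom rods.
#' @return a `bos_mask`: a [bos_volume] whose voxels are logical.
#' @export
segment_femur <- function(volume, density_threshold_mg_cm3 = 150,
                          closing_radius_mm = 2, rod_masks = NULL) {
  if (density_threshold_mg_cm3 <= 0) stop("threshold must be positive")
  thr <- volume$voxels >= density_threshold_mg_cm3
  if (!any(thr)) stop("no bone found: empty mask after thresholding")
  lab <- cc_label26_cpp(thr)
  counts <- tabulate(lab[lab > 0L])
  order_by_size <- order(counts, decreasing = TRUE)
  chosen <- 0L
  for (cand in order_by_size) {
    in_rod <- FALSE
    if (!is.null(rod_masks))
      for (rm in rod_masks)
        if (any(lab[rm] == cand)) { in_rod <- TRUE; break }
    if (!in_rod) { chosen <- cand; break }
  }
  if (chosen == 0L) stop("no bone found: all components overlap phantom rods")
  mask <- array(lab == chosen, dim = dim(volume$voxels))
  mask <- binary_close(mask, closing_radius_mm, volume$spacing)
  mask <- fill_holes_cpp(mask)
  out <- bos_volume(mask, spacing = volume$spacing, affine = volume$affine,
                    units = "mask")
  out$ground_truth <- volume$ground_truth
  class(out) <- c("bos_mask", class(out))
  out
}

#' Physical volume of a mask
#' @param mask a `bos_mask` or logical array with a `spacing` attribute.
#' @param spacing_mm voxel spacing, taken from the object when absent.
#' @return volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask, spacing_mm = NULL) {
  if (inherits(mask, "bos_volume")) {
    spacing_mm <- mask$spacing
    mask <- mask$voxels
  }
  sum(mask) * prod(spacing_mm)
}
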