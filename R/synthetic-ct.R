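#' CT acquisition protocol
#'
#' Container for the protocolled scan settings a strength-score request must
#' comply with.  The defaults are the validated radiotherapy-planning
#' protocol: 120 kVp, 3 mm slices, pitch 1.5, 480 mm field of view and a
#' 0.9375 mm in-plane resolution.
#'
#' @param tube_voltage_kVp tube voltage (kVp).
#' @param slice_thickness_mm slice thickness (mm).
#' @param pitch helical pitch (dimensionless).
#' @param fov_mm field of view (mm).
#' @param in_plane_resolution_mm in-plane pixel size (mm).
#' @return object of class `ct_protocol`.
#' @export
ct_protocol <- function(tube_voltage_kVp = 120, slice_thickness_mm = 3,
                        pitch = 1.5, fov_mm = 480,
                        in_plane_resolution_mm = 0.9375) {
  vals <- c(tube_voltage_kVp, slice_thickness_mm, pitch, fov_mm,
            in_plane_resolution_mm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all CT protocol parameters must be strictly positive")
  structure(list(tube_voltage_kVp = tube_voltage_kVp,
                 slice_thickness_mm = slice_thickness_mm, pitch = pitch,
                 fov_mm = fov_mm,
                 in_plane_resolution_mm = in_plane_resolution_mm),
            class = "ct_protocol")
}

#' Calibration phantom specification
#'
#' A solid phantom with cylindrical rods of known calcium-equivalent density
#' scanned in the same field of view as the patient.  Rod axes run along the
#' world z axis.
#'
#' @param rod_densities_mg_cm3 known densities, one per rod (>= 2 distinct
#'   values are needed for a calibration line).
#' @param rod_radius_mm rod radius (mm).
#' @param rod_centers n x 2 matrix (or length-2 vector for one rod) of rod
#'   axis positions in world (x, y) mm.  Default: rods in a row well below
#'   the femur.
#' @param rod_z_range_mm length-2 z extent of the rods, or `NULL` to span the
#'   whole volume.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(rod_densities_mg_cm3 = c(0, 50, 100, 200),
                         rod_radius_mm = 6, rod_centers = NULL,
                         rod_z_range_mm = NULL) {
  if (length(rod_densities_mg_cm3) < 2 ||
      length(unique(rod_densities_mg_cm3)) < 2)
    stop("phantom needs at least two rods with distinct densities")
  if (any(rod_densities_mg_cm3 < 0)) stop("rod densities must be >= 0")
  if (rod_radius_mm <= 0) stop("rod radius must be positive")
  n <- length(rod_densities_mg_cm3)
  if (is.null(rod_centers)) {
    rod_centers <- cbind(seq(-1.5, 1.5, length.out = n) * 4 * rod_radius_mm,
                         -60)
  }
  rod_centers <- matrix(rod_centers, ncol = 2)
  if (nrow(rod_centers) != n)
    stop("need one rod center per rod density")
  structure(list(rod_densities_mg_cm3 = as.numeric(rod_densities_mg_cm3),
                 rod_radius_mm = rod_radius_mm, rod_centers = rod_centers,
                 rod_z_range_mm = rod_z_range_mm),
            class = "phantom_spec")
}

#' Idealized femur specification
#'
#' The synthetic femur is a capped cylinder (diaphysis: cortical shell with a
#' trabecular core, long axis along +z, distal end at z = 0) topped by an
#' offset sphere standing in for the femoral head.  An optional spherical
#' low-density lesion emulates an osteolytic metastasis.
#'
#' @param shaft_length_mm,shaft_outer_radius_mm,cortical_thickness_mm shaft
#'   geometry (mm).
#' @param head_radius_mm femoral head sphere radius (mm).
#' @param head_center_offset length-3 offset (mm) of the head center from the
#'   proximal end of the shaft axis, `(x, y, z)`.
#' @param cortical_density_mg_cm3,trabecular_density_mg_cm3 tissue densities.
#' @param lesion `NULL` or `list(center = c(x, y, z), radius_mm, density_mg_cm3)`
#'   in world coordinates; must lie fully inside the bone.
#' @return object of class `femur_spec`.
#' @export
femur_spec <- function(shaft_length_mm = 120, shaft_outer_radius_mm = 16,
                       cortical_thickness_mm = 4, head_radius_mm = 22,
                       head_center_offset = c(20, 0, 12),
                       cortical_density_mg_cm3 = 800,
                       trabecular_density_mg_cm3 = 300, lesion = NULL) {
  if (cortical_thickness_mm >= shaft_outer_radius_mm)
    stop("cortical thickness must be smaller than the shaft radius")
  if (!(cortical_density_mg_cm3 > trabecular_density_mg_cm3))
    stop("cortical density must exceed trabecular density")
  if (!is.null(lesion)) {
    stopifnot(is.list(lesion), length(lesion$center) == 3,
              lesion$radius_mm > 0)
    if (lesion$density_mg_cm3 < 0) stop("lesion density must be >= 0")
    if (!(lesion$density_mg_cm3 < trabecular_density_mg_cm3))
      stop("an osteolytic lesion must be less dense than trabecular bone")
  }
  structure(list(shaft_length_mm = shaft_length_mm,
                 shaft_outer_radius_mm = shaft_outer_radius_mm,
                 cortical_thickness_mm = cortical_thickness_mm,
                 head_radius_mm = head_radius_mm,
                 head_center_offset = as.numeric(head_center_offset),
                 cortical_density_mg_cm3 = cortical_density_mg_cm3,
                 trabecular_density_mg_cm3 = trabecular_density_mg_cm3,
                 lesion = lesion),
            class = "femur_spec")
}

#' World position of the synthetic femoral head center
#' @param femur a [femur_spec].
#' @return length-3 numeric.
#' @export
femur_head_center <- function(femur) {
  c(femur$head_center_offset[1], femur$head_center_offset[2],
    femur$shaft_length_mm + femur$head_center_offset[3])
}

# Analytic solid volume of the idealized femur (shaft cylinder + head sphere
# minus their lens-shaped overlap), mm^3.
femur_analytic_volume <- function(femur) {
  L <- femur$shaft_length_mm
  R <- femur$shaft_outer_radius_mm
  rh <- femur$head_radius_mm
  v_shaft <- pi * R^2 * L
  v_head <- 4 / 3 * pi * rh^3
  # overlap estimated numerically: sample the head sphere on a fine grid and
  # count points inside the shaft (deterministic midpoint rule)
  h <- rh / 24
  gx <- seq(-rh + h / 2, rh - h / 2, by = h)
  ctr <- femur_head_center(femur)
  pts <- expand.grid(x = gx + ctr[1], y = gx + ctr[2], z = gx + ctr[3])
  inside_head <- (pts$x - ctr[1])^2 + (pts$y - ctr[2])^2 +
    (pts$z - ctr[3])^2 <= rh^2
  inside_shaft <- pts$x^2 + pts$y^2 <= R^2 & pts$z >= 0 & pts$z <= L
  v_overlap <- sum(inside_head & inside_shaft) * h^3
  v_shaft + v_head - v_overlap
}

# Membership tests on an n x 3 matrix of world points.  Returns a list of
# logical vectors (femur, interior, lesion).
femur_membership <- function(femur, xyz) {
  L <- femur$shaft_length_mm
  R <- femur$shaft_outer_radius_mm
  t <- femur$cortical_thickness_mm
  rh <- femur$head_radius_mm
  ctr <- femur_head_center(femur)
  r2 <- xyz[, 1]^2 + xyz[, 2]^2
  in_shaft <- r2 <= R^2 & xyz[, 3] >= 0 & xyz[, 3] <= L
  d2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 + (xyz[, 3] - ctr[3])^2
  in_head <- d2 <= rh^2
  shaft_int <- r2 <= (R - t)^2 & xyz[, 3] >= t & xyz[, 3] <= L
  head_int <- d2 <= (rh - t)^2
  femur_in <- in_shaft | in_head
  interior <- (shaft_int | head_int) & femur_in
  lesion_in <- rep(FALSE, nrow(xyz))
  if (!is.null(femur$lesion)) {
    lc <- femur$lesion$center
    lesion_in <- (xyz[, 1] - lc[1])^2 + (xyz[, 2] - lc[2])^2 +
      (xyz[, 3] - lc[3])^2 <= femur$lesion$radius_mm^2
  }
  list(femur = femur_in, interior = interior, lesion = lesion_in)
}

rod_membership <- function(phantom, xyz) {
  lapply(seq_along(phantom$rod_densities_mg_cm3), function(k) {
    c2 <- phantom$rod_centers[k, ]
    hit <- (xyz[, 1] - c2[1])^2 + (xyz[, 2] - c2[2])^2 <=
      phantom$rod_radius_mm^2
    if (!is.null(phantom$rod_z_range_mm))
      hit <- hit & xyz[, 3] >= phantom$rod_z_range_mm[1] &
        xyz[, 3] <= phantom$rod_z_range_mm[2]
    hit
  })
}

#' Generate a synthetic CT volume of a femur plus calibration phantom
#'
#' Voxelizes the idealized femur (with optional lytic lesion) and the phantom
#' rods onto a regular grid and maps density to Hounsfield units through a
#' known affine law, `HU = slope * rho + intercept + N(0, noise_sd)`.  The
#' generating mapping, specs and seed are retained as ground truth so
#' downstream stages can be verified exactly.
#'
#' @param femur a [femur_spec].
#' @param phantom a [phantom_spec] or `NULL` for a phantom-free scan.
#' @param protocol a [ct_protocol]; sets the default voxel spacing
#'   (in-plane resolution, in-plane resolution, slice thickness).
#' @param slope,intercept HU per (mg/cm^3), and HU offset of the mapping.
#' @param noise_sd additive i.i.d. Gaussian noise in HU (0 = noiseless).
#' @param seed RNG seed; mandatory when `noise_sd > 0`.
#' @param spacing_mm optional length-3 voxel spacing override.
#' @param margin_mm air margin around the scene.
#' @param rotation optional 3x3 rotation applied to the scene about the
#'   femur's mid-axis point (exercises the stance-alignment stage).
#' @return a `bos_raw_volume` (a [bos_volume] of HU values with a
#'   `ground_truth` element).
#' @export
generate_phantom_volume <- function(femur, phantom = phantom_spec(),
                                    protocol = ct_protocol(), slope = 1,
                                    intercept = 0, noise_sd = 0, seed = NULL,
                                    spacing_mm = NULL, margin_mm = 10,
                                    rotation = NULL) {
  stopifnot(inherits(femur, "femur_spec"))
  if (!is.null(phantom)) stopifnot(inherits(phantom, "phantom_spec"))
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required when noise_sd > 0")
  if (is.null(spacing_mm))
    spacing_mm <- c(protocol$in_plane_resolution_mm,
                    protocol$in_plane_resolution_mm,
                    protocol$slice_thickness_mm)
  # world bounding box of the scene (pre-rotation)
  ctr <- femur_head_center(femur)
  R <- femur$shaft_outer_radius_mm
  rh <- femur$head_radius_mm
  lo <- c(min(-R, ctr[1] - rh), min(-R, ctr[2] - rh), 0)
  hi <- c(max(R, ctr[1] + rh), max(R, ctr[2] + rh), ctr[3] + rh)
  if (!is.null(phantom)) {
    lo[1:2] <- pmin(lo[1:2], apply(phantom$rod_centers, 2, min) -
                      phantom$rod_radius_mm)
    hi[1:2] <- pmax(hi[1:2], apply(phantom$rod_centers, 2, max) +
                      phantom$rod_radius_mm)
  }
  pivot <- c(0, 0, femur$shaft_length_mm / 2)
  if (!is.null(rotation)) {
    # expand the box to hold the rotated scene
    corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                     c(lo[3], hi[3])))
    rc <- sweep(sweep(corners, 2, pivot) %*% t(rotation), 2, pivot, "+")
    lo <- apply(rc, 2, min)
    hi <- apply(rc, 2, max)
  }
  lo <- lo - margin_mm
  hi <- hi + margin_mm
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing_mm)) + 1L)
  affine <- diag(c(spacing_mm, 1))
  affine[1:3, 4] <- lo
  vol <- bos_volume(array(0, dim = dims), spacing_mm, affine, units = "HU")
  xyz <- voxel_center_grid(vol)
  if (!is.null(rotation)) {
    # scene rotated by Q <=> sample the unrotated scene at Q^T (x - pivot) + pivot
    xyz_geo <- sweep(sweep(xyz, 2, pivot) %*% rotation, 2, pivot, "+")
  } else {
    xyz_geo <- xyz
  }
  mem <- femur_membership(femur, xyz_geo)
  rho <- numeric(nrow(xyz))
  rho[mem$femur] <- ifelse(mem$interior[mem$femur],
                           femur$trabecular_density_mg_cm3,
                           femur$cortical_density_mg_cm3)
  if (!is.null(femur$lesion)) {
    if (any(mem$lesion & !mem$femur))
      stop("lesion extends outside the bone")
    rho[mem$lesion] <- femur$lesion$density_mg_cm3
  }
  rods <- list()
  if (!is.null(phantom)) {
    rods <- rod_membership(phantom, xyz_geo)
    for (k in seq_along(rods)) {
      if (any(rods[[k]] & mem$femur))
        stop("phantom rod ", k, " overlaps the femur")
      rho[rods[[k]]] <- phantom$rod_densities_mg_cm3[k]
    }
  }
  hu <- slope * rho + intercept
  if (noise_sd > 0) {
    set.seed(seed)
    hu <- hu + stats::rnorm(length(hu), sd = noise_sd)
  }
  vol$voxels <- array(hu, dim = dims)
  vol$ground_truth <- list(slope = slope, intercept = intercept,
                           noise_sd = noise_sd, seed = seed, femur = femur,
                           phantom = phantom, protocol = protocol,
                           rotation = rotation, pivot = pivot)
  class(vol) <- c("bos_raw_volume", class(vol))
  vol
}

#' Ground-truth masks of a synthetic volume
#'
#' Recomputes, analytically on the volume's own grid, the boolean femur,
#' lesion and per-rod masks of a volume produced by
#' [generate_phantom_volume()].  These serve as oracles for the segmentation
#' and calibration stages.
#'
#' @param volume a `bos_raw_volume`.
#' @return list with elements `femur`, `lesion` (logical arrays; `lesion` is
#'   all-`FALSE` without a lesion) and `rods` (list of logical arrays).
#' @export
ground_truth_masks <- function(volume) {
  gt <- volume$ground_truth
  if (is.null(gt)) stop("volume carries no ground truth")
  xyz <- voxel_center_grid(volume)
  if (!is.null(gt$rotation))
    xyz <- sweep(sweep(xyz, 2, gt$pivot) %*% gt$rotation, 2, gt$pivot, "+")
  d <- dim(volume$voxels)
  mem <- femur_membership(gt$femur, xyz)
  rods <- list()
  if (!is.null(gt$phantom))
    rods <- lapply(rod_membership(gt$phantom, xyz), array, dim = d)
  list(femur = array(mem$femur, dim = d),
       lesion = array(mem$lesion & mem$femur, dim = d),
       rods = rods)
}

#' Synthetic scan presets
#'
#' Three canonical scenes at a desk-scale 2 mm isotropic resolution: an
#' intact femur, and femurs carrying a small (6 mm) or large (12 mm) lytic
#' lesion centered in the femoral head.
#'
#' @param name preset name.
#' @param seed RNG seed (used when `noise_sd > 0`).
#' @param noise_sd HU noise level.
#' @param spacing_mm voxel spacing (isotropic default 2 mm).
#' @return a `bos_raw_volume`.
#' @export
synth_preset <- function(name = c("intact", "lytic-small", "lytic-large"),
                         seed = 1, noise_sd = 0, spacing_mm = c(2, 2, 2)) {
  name <- match.arg(name)
  fem <- femur_spec()
  hc <- femur_head_center(fem)
  fem$lesion <- switch(name,
    "intact" = NULL,
    "lytic-small" = list(center = hc, radius_mm = 6, density_mg_cm3 = 50),
    "lytic-large" = list(center = hc, radius_mm = 12, density_mg_cm3 = 50))
  generate_phantom_volume(fem, phantom_spec(), slope = 1.2, intercept = -5,
                          noise_sd = noise_sd, seed = seed,
                          spacing_mm = spacing_mm)
}

#' Dice overlap coefficient between two masks
#' @param a,b logical arrays of identical dimension.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
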