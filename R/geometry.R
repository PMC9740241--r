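#' Least-squares sphere fit
#'
#' Algebraic fit: `|x|^2 = 2 c . x + (r^2 - |c|^2)` is linear in `(c, d)`.
#'
#' @param pts n x 3 matrix of points.
#' @return list with `center`, `radius`, `rms` (root-mean-square radial
#'   residual).
#' @export
fit_sphere <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 4) stop("sphere fit needs at least 4 points")
  A <- cbind(2 * pts, 1)
  y <- rowSums(pts^2)
  b <- qr.solve(A, y)
  center <- b[1:3]
  radius <- sqrt(max(b[4] + sum(center^2), 0))
  d <- sqrt(rowSums(sweep(pts, 2, center)^2))
  list(center = unname(center), radius = radius,
       rms = sqrt(mean((d - radius)^2)))
}

mask_surface_voxels <- function(mask_arr) {
  se6 <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0,
                  0, 0, 1, 0, 0, -1, 0, 0, 0),
                ncol = 3, byrow = TRUE)
  storage.mode(se6) <- "integer"
  mask_arr & !morph_cpp(mask_arr, se6, grow = FALSE)
}

mask_world_coords <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE)
  voxel_to_world(mask, idx)
}

#' Locate the femoral head by sphere fitting
#'
#' Fits a sphere to the surface voxels in the extreme quartile of the mask's
#' long (first principal) axis.  Both ends are tried and the better fit wins,
#' so no anatomical orientation of the scan is assumed.
#'
#' @param mask a `bos_mask` from [segment_femur()].
#' @param rms_tol_rel maximum accepted RMS radial residual as a fraction of
#'   the fitted radius (default 0.06; voxelized spheres fit at about 0.03,
#'   while a capped cylinder end fits no better than about 0.10).
#' @return list with `center` (world mm), `radius` (mm), `rms`.
#' @export
find_head_center <- function(mask, rms_tol_rel = 0.06) {
  surf <- mask_surface_voxels(mask$voxels)
  svol <- mask
  svol$voxels <- surf
  pts <- mask_world_coords(svol)
  ctr <- colMeans(pts)
  ax <- stats::prcomp(pts, center = TRUE)$rotation[, 1]
  proj <- as.numeric(sweep(pts, 2, ctr) %*% ax)
  q <- stats::quantile(proj, c(0.25, 0.75))
  fits <- lapply(list(proj <= q[1], proj >= q[2]), function(sel) {
    if (sum(sel) < 10) return(NULL)
    fit_sphere(pts[sel, , drop = FALSE])
  })
  fits <- Filter(function(f) !is.null(f) && f$radius > 2 * max(mask$spacing),
                 fits)
  if (length(fits) == 0) stop("no spherical head found")
  best <- fits[[which.min(vapply(fits, function(f) f$rms / f$radius,
                                 numeric(1)))]]
  if (best$rms / best$radius > rms_tol_rel)
    stop(sprintf("no spherical head found (RMS residual %.2f mm at radius %.1f mm)",
                 best$rms, best$radius))
  best
}

#' Locate the knee (distal) center
#'
#' Centroid of the distal-most 5 mm slab of the mask along its long axis,
#' the distal end being the one farther from the head center.
#'
#' @param mask a `bos_mask`.
#' @param head_center world position of the femoral head center.
#' @param slab_mm slab thickness (default 5 mm).
#' @return length-3 world point (mm).
#' @export
find_knee_center <- function(mask, head_center, slab_mm = 5) {
  pts <- mask_world_coords(mask)
  ctr <- colMeans(pts)
  ax <- stats::prcomp(pts, center = TRUE)$rotation[, 1]
  proj <- as.numeric(sweep(pts, 2, ctr) %*% ax)
  head_proj <- sum((head_center - ctr) * ax)
  if (head_proj < mean(range(proj))) proj <- -proj  # distal = far from head
  sel <- proj <= min(proj) + slab_mm
  colMeans(pts[sel, , drop = FALSE])
}

rotation_between <- function(a, b) {
  # smallest rotation taking unit vector a onto unit vector b (Rodrigues)
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {
    # opposite vectors: rotate pi about any axis orthogonal to a
    w <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- w - sum(w * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

#' Align the femur to stance and crop the proximal part
#'
#' Rigidly rotates the scene so the head-center-to-knee-center axis becomes
#' the loading (z) axis, with the head center at the origin and the knee on
#' the negative z axis, then keeps the proximal half.  If a lesion extends
#' below the mid-plane the crop is moved distally to include it plus one
#' element-size margin.  Density is resampled trilinearly, the mask by
#' nearest neighbour.
#'
#' @param volume calibrated density volume.
#' @param mask femur mask on the same grid.
#' @param head_center,knee_center world points (mm).
#' @param lesion_points optional n x 3 matrix of world points whose aligned
#'   extent must survive the crop (e.g. lesion mask voxel centers).
#' @param crop keep only the proximal part? (`FALSE` retains the whole bone.)
#' @param margin_mm element-size margin added below the crop plane and
#'   laterally around the bone.
#' @return an `aligned_femur`: list of `volume`, `mask` (aligned grids),
#'   `head_center`, `knee_center`, `crop_plane_z`, `rotation`.
#' @export
align_and_crop <- function(volume, mask, head_center, knee_center,
                           lesion_points = NULL, crop = TRUE, margin_mm = 3) {
  axis <- knee_center - head_center
  L <- sqrt(sum(axis^2))
  if (L < 1e-9) stop("head and knee centers coincide")
  Q <- rotation_between(axis, c(0, 0, -1))
  to_aligned <- function(x) sweep(x, 2, head_center) %*% t(Q)
  pts <- to_aligned(mask_world_coords(mask))
  lo <- apply(pts, 2, min) - margin_mm
  hi <- apply(pts, 2, max) + margin_mm
  crop_z <- -L / 2
  if (!is.null(lesion_points) && nrow(lesion_points) > 0) {
    lz <- min(to_aligned(rbind_matrix(lesion_points))[, 3])
    crop_z <- min(crop_z, lz - margin_mm)
  }
  if (crop) lo[3] <- max(lo[3], crop_z)
  sp <- volume$spacing
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / sp)) + 1L)
  affine <- diag(c(sp, 1))
  affine[1:3, 4] <- lo
  avol <- bos_volume(array(0, dim = dims), sp, affine, units = volume$units)
  xyz <- voxel_center_grid(avol)
  src <- sweep(xyz %*% Q, 2, head_center, "+")  # inverse map to source world
  avol$voxels <- array(sample_trilinear(volume, src, fill = 0), dim = dims)
  amask <- bos_volume(array(sample_nearest(mask, src, fill = 0) > 0.5,
                            dim = dims), sp, affine, units = "mask")
  class(amask) <- c("bos_mask", class(amask))
  structure(list(volume = avol, mask = amask,
                 head_center = c(0, 0, 0), knee_center = c(0, 0, -L),
                 crop_plane_z = if (crop) crop_z else NA_real_,
                 rotation = Q),
            class = "aligned_femur")
}
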