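#' Fit the HU-to-density calibration line from phantom rods
#'
#' Ordinary least squares of the known calcium-equivalent rod densities on
#' the mean Hounsfield unit inside each rod.  Regressing density on HU (not
#' the reverse) makes application a direct affine map, the standard
#' quantitative-CT convention.  Rod means are taken over a one-voxel-eroded
#' mask to exclude partial-volume rims; if erosion would empty a rod the full
#' mask is used.
#'
#' @param volume a [bos_volume] of HU values.
#' @param rod_masks list of logical arrays, one per rod, on the volume grid.
#' @param known_densities_mg_cm3 known rod densities (mg/cm^3).
#' @param erode_voxels rim erosion depth in voxels (default 1).
#' @return object of class `calibration_fit` with fields
#'   `slope_mg_cm3_per_HU`, `intercept_mg_cm3`, `r_squared` and `rod_samples`
#'   (data frame of known density, mean HU, voxel count).
#' @export
fit_calibration <- function(volume, rod_masks, known_densities_mg_cm3,
                            erode_voxels = 1) {
  if (length(rod_masks) < 2) stop("calibration needs at least two rods")
  if (length(rod_masks) != length(known_densities_mg_cm3))
    stop("need one known density per rod mask")
  if (length(unique(known_densities_mg_cm3)) < 2)
    stop("known rod densities must not all be equal")
  se6 <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0,
                  0, 0, 1, 0, 0, -1, 0, 0, 0),
                ncol = 3, byrow = TRUE)
  storage.mode(se6) <- "integer"
  samples <- lapply(seq_along(rod_masks), function(k) {
    m <- rod_masks[[k]]
    if (!any(m)) stop("rod mask ", k, " is empty")
    if (erode_voxels > 0) {
      me <- m
      for (i in seq_len(erode_voxels)) me <- morph_cpp(me, se6, grow = FALSE)
      if (any(me)) m <- me
    }
    c(mean_hu = mean(volume$voxels[m]), n = sum(m))
  })
  mean_hu <- vapply(samples, `[[`, numeric(1), "mean_hu")
  nvox <- vapply(samples, `[[`, numeric(1), "n")
  if (max(mean_hu) - min(mean_hu) < 1e-12)
    stop("degenerate calibration: all rod HU means are equal")
  fit <- stats::lm(rho ~ hu,
                   data = data.frame(rho = known_densities_mg_cm3,
                                     hu = mean_hu))
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0)
    stop("calibration slope is not positive; higher HU must mean denser bone")
  ss_tot <- sum((known_densities_mg_cm3 - mean(known_densities_mg_cm3))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(
    slope_mg_cm3_per_HU = slope,
    intercept_mg_cm3 = unname(stats::coef(fit)[1]),
    r_squared = r2,
    rod_samples = data.frame(known_density_mg_cm3 = known_densities_mg_cm3,
                             mean_hu = mean_hu, n_voxels = nvox),
    lm = fit
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> density = %.6g + %.6g * HU  (r^2 = %.4f, %d rods)\n",
    x$intercept_mg_cm3, x$slope_mg_cm3_per_HU, x$r_squared,
    nrow(x$rod_samples)))
  invisible(x)
}

#' Apply a calibration fit to an HU volume
#'
#' Per-voxel affine transform followed by clamping at zero: calcium-
#' equivalent density is physical and the downstream material map requires
#' non-negative input.  Grid metadata is preserved.
#'
#' @param volume a [bos_volume] of HU values.
#' @param fit a `calibration_fit`.
#' @return a `bos_calibrated_volume` ([bos_volume] of mg/cm^3 densities with
#'   the fit attached as `provenance`).
#' @export
apply_calibration <- function(volume, fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  out <- bos_volume(
    array(pmax(0, fit$intercept_mg_cm3 +
                 fit$slope_mg_cm3_per_HU * volume$voxels),
          dim = dim(volume$voxels)),
    spacing = volume$spacing, affine = volume$affine, units = "mg/cm^3")
  out$provenance <- fit[c("slope_mg_cm3_per_HU", "intercept_mg_cm3",
                          "r_squared")]
  out$ground_truth <- volume$ground_truth  # carried through for oracle tests
  class(out) <- c("bos_calibrated_volume", class(out))
  out
}
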