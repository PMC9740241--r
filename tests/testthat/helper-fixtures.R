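# Fixtures shared across test files.  Everything is generated in code; the
# synthetic scenes are small (coarse spacing) to keep the suite fast.

# A rectangular box pre-packaged like an aligned femur, for meshing and
# solver oracles: nx x ny x nz voxels of edge h (mm), uniform density.
box_aligned <- function(nx, ny, nz, h = 1, density = 300) {
  dims <- c(nx, ny, nz)
  list(mask = bos_volume(array(TRUE, dim = dims), rep(h, 3), units = "mask"),
       volume = bos_volume(array(density, dim = dims), rep(h, 3),
                           units = "mg/cm^3"))
}

# Uniform hand-set material field (bypasses the density law).
uniform_materials <- function(mesh, E = 1000, nu = 0, sigma_y = Inf, H = 0) {
  m <- nrow(mesh$elements)
  structure(list(E_MPa = rep(E, m), nu = rep(nu, m),
                 sigma_y_MPa = rep(sigma_y, m), H_MPa = rep(H, m)),
            class = "material_field")
}

# Node sets on the extreme z planes of a mesh.
z_plane_nodes <- function(mesh, top = TRUE, tol = 1e-9) {
  z <- mesh$nodes[, 3]
  if (top) which(z > max(z) - tol) else which(z < min(z) + tol)
}

# A small femur scene used by segmentation/geometry tests: half-size bone at
# 2 mm isotropic spacing so the whole suite stays fast.
small_femur_spec <- function(lesion = NULL) {
  femur_spec(shaft_length_mm = 70, shaft_outer_radius_mm = 12,
             cortical_thickness_mm = 3.5, head_radius_mm = 15,
             head_center_offset = c(13, 0, 8), lesion = lesion)
}

small_scene <- function(lesion = NULL, noise_sd = 0, seed = 1,
                        phantom = phantom_spec(), spacing = c(2, 2, 2),
                        rotation = NULL) {
  generate_phantom_volume(small_femur_spec(lesion), phantom,
                          slope = 1.2, intercept = -5, noise_sd = noise_sd,
                          seed = seed, spacing_mm = spacing,
                          rotation = rotation)
}

# Calibrated density volume + ground truth for a small scene.
small_calibrated <- function(...) {
  v <- small_scene(...)
  gt <- ground_truth_masks(v)
  fit <- fit_calibration(v, gt$rods,
                         v$ground_truth$phantom$rod_densities_mg_cm3)
  list(volume = apply_calibration(v, fit), raw = v, gt = gt, fit = fit)
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

rotation_y <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
}
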