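test_that("identity mapping gives HU numerically equal to density", {
  v <- small_scene()
  gt <- ground_truth_masks(v)
  ident <- generate_phantom_volume(small_femur_spec(), phantom_spec(),
                                   slope = 1, intercept = 0,
                                   spacing_mm = c(2, 2, 2))
  expect_setequal(unique(as.numeric(ident$voxels)),
                  c(0, 50, 100, 200, 300, 800))
  expect_true(all(ident$voxels[gt$femur] %in% c(300, 800)))
})

test_that("the affine HU law holds inside a known rod", {
  ph <- phantom_spec(rod_densities_mg_cm3 = c(0, 200), rod_radius_mm = 6)
  v <- generate_phantom_volume(small_femur_spec(), ph, slope = 1.5,
                               intercept = 10, spacing_mm = c(2, 2, 2))
  gt <- ground_truth_masks(v)
  expect_equal(mean(v$voxels[gt$rods[[2]]]), 310)
  expect_equal(mean(v$voxels[gt$rods[[1]]]), 10)
})

test_that("lesion voxel count matches the analytic sphere volume", {
  les <- list(center = c(0, 0, 35), radius_mm = 5, density_mg_cm3 = 50)
  fem <- femur_spec(shaft_length_mm = 70, shaft_outer_radius_mm = 12,
                    cortical_thickness_mm = 3, lesion = les)
  v <- generate_phantom_volume(fem, phantom = NULL, spacing_mm = c(1, 1, 1))
  gt <- ground_truth_masks(v)
  analytic <- 4 / 3 * pi * 5^3
  expect_lt(abs(sum(gt$lesion) - analytic) / analytic, 0.10)
})

test_that("ground-truth masks satisfy their containment contracts", {
  les <- list(center = c(13, 0, 78), radius_mm = 6, density_mg_cm3 = 50)
  v <- small_scene(lesion = les)
  gt <- ground_truth_masks(v)
  expect_gt(sum(gt$femur), 0)
  lab <- bosscore:::cc_label26_cpp(gt$femur)
  expect_equal(max(lab), 1L)  # femur mask is a single connected component
  expect_true(all(gt$femur[gt$lesion]))  # lesion inside femur
  for (i in seq_along(gt$rods))
    for (j in seq_along(gt$rods))
      if (i < j) expect_false(any(gt$rods[[i]] & gt$rods[[j]]))
})

test_that("invalid scenes are rejected", {
  # lesion poking outside the bone
  les <- list(center = c(0, 0, 0), radius_mm = 8, density_mg_cm3 = 50)
  expect_error(small_scene(lesion = les), "outside the bone")
  # rod placed through the femur
  ph <- phantom_spec(rod_densities_mg_cm3 = c(0, 100),
                     rod_centers = rbind(c(0, 0), c(0, -60)))
  expect_error(generate_phantom_volume(small_femur_spec(), ph,
                                       spacing_mm = c(2, 2, 2)),
               "overlaps the femur")
  # noise without a seed
  expect_error(generate_phantom_volume(small_femur_spec(), phantom_spec(),
                                       noise_sd = 5, spacing_mm = c(2, 2, 2)),
               "seed")
})

test_that("generation is deterministic given a seed", {
  a <- small_scene(noise_sd = 5, seed = 11)
  b <- small_scene(noise_sd = 5, seed = 11)
  expect_identical(a$voxels, b$voxels)
  c <- small_scene(noise_sd = 5, seed = 12)
  expect_false(identical(a$voxels, c$voxels))
})

test_that("noiseless HU histogram is exactly the mapped density set", {
  v <- small_scene()  # slope 1.2, intercept -5
  dens <- c(0, 50, 100, 200, 300, 800)
  expect_setequal(unique(as.numeric(v$voxels)),
                  unique(1.2 * c(0, v$ground_truth$phantom$rod_densities_mg_cm3,
                                 300, 800) - 5))
})

test_that("femur mask volume matches the analytic solid volume at 1 mm", {
  fem <- femur_spec(shaft_length_mm = 60, shaft_outer_radius_mm = 12,
                    cortical_thickness_mm = 3, head_radius_mm = 15,
                    head_center_offset = c(12, 0, 6))
  v <- generate_phantom_volume(fem, phantom = NULL, spacing_mm = c(1, 1, 1))
  gt <- ground_truth_masks(v)
  vol_mask <- mask_volume_mm3(gt$femur, v$spacing)
  vol_true <- bosscore:::femur_analytic_volume(fem)
  expect_lt(abs(vol_mask - vol_true) / vol_true, 0.05)
})
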