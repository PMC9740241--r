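test_that("an exact line through the rod samples is recovered", {
  # three collinear rods: HU = 1.5 rho + 10  =>  rho = (HU - 10) / 1.5
  dims <- c(12, 4, 4)
  vol <- bos_volume(array(0, dims), c(1, 1, 1), units = "HU")
  masks <- lapply(0:2, function(k) {
    m <- array(FALSE, dims)
    m[k * 4 + 1:4, , ] <- TRUE
    m
  })
  hu <- c(10, 160, 310)
  for (k in 1:3) vol$voxels[masks[[k]]] <- hu[k]
  fit <- fit_calibration(vol, masks, c(0, 100, 200), erode_voxels = 0)
  expect_equal(fit$slope_mg_cm3_per_HU, 1 / 1.5, tolerance = 1e-12)
  expect_equal(fit$intercept_mg_cm3, -10 / 1.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(apply_calibration(vol, fit)$voxels[masks[[3]]],
               rep(200, sum(masks[[3]])), tolerance = 1e-12)
})

test_that("identity generation yields an identity fit, invariant to rod order", {
  v <- small_scene()  # slope 1.2, intercept -5
  gt <- ground_truth_masks(v)
  dens <- v$ground_truth$phantom$rod_densities_mg_cm3
  fit <- fit_calibration(v, gt$rods, dens)
  expect_equal(fit$slope_mg_cm3_per_HU, 1 / 1.2, tolerance = 1e-10)
  expect_equal(fit$intercept_mg_cm3, 5 / 1.2, tolerance = 1e-10)
  perm <- c(3, 1, 4, 2)
  fit2 <- fit_calibration(v, gt$rods[perm], dens[perm])
  expect_equal(fit2$slope_mg_cm3_per_HU, fit$slope_mg_cm3_per_HU)
  expect_equal(fit2$intercept_mg_cm3, fit$intercept_mg_cm3)
})

test_that("noiseless round trip reproduces the density field to machine precision", {
  cal <- small_calibrated()
  v <- cal$raw
  xyz <- bosscore:::voxel_center_grid(v)
  mem <- bosscore:::femur_membership(v$ground_truth$femur, xyz)
  truth <- numeric(nrow(xyz))
  truth[mem$femur] <- ifelse(mem$interior[mem$femur], 300, 800)
  for (k in seq_along(cal$gt$rods))
    truth[cal$gt$rods[[k]]] <-
      v$ground_truth$phantom$rod_densities_mg_cm3[k]
  expect_equal(as.numeric(cal$volume$voxels), truth, tolerance = 1e-9)
})

test_that("calibration is clamped at zero and preserves the grid", {
  cal <- small_calibrated()
  expect_true(all(cal$volume$voxels >= 0))
  expect_identical(dim(cal$volume$voxels), dim(cal$raw$voxels))
  expect_equal(cal$volume$affine, cal$raw$affine)
  # HU far below the intercept maps to 0
  low <- cal$raw
  low$voxels[] <- -2000
  expect_true(all(apply_calibration(low, cal$fit)$voxels == 0))
})

test_that("degenerate rod sets are rejected", {
  dims <- c(8, 4, 4)
  vol <- bos_volume(array(5, dims), c(1, 1, 1), units = "HU")
  m1 <- array(FALSE, dims); m1[1:4, , ] <- TRUE
  m2 <- array(FALSE, dims); m2[5:8, , ] <- TRUE
  expect_error(fit_calibration(vol, list(m1), 100), "two rods")
  expect_error(fit_calibration(vol, list(m1, m2), c(100, 100), "equal"))
  # equal HU but different densities -> degenerate
  expect_error(fit_calibration(vol, list(m1, m2), c(0, 100), erode_voxels = 0),
               "degenerate")
  # negative relation (higher HU, lower density) -> monotonicity error
  vol$voxels[m2] <- 500
  expect_error(fit_calibration(vol, list(m1, m2), c(100, 0), erode_voxels = 0),
               "not positive")
})

test_that("noisy fits fall in the closed-form OLS interval at the nominal rate", {
  # Rod mean HU carries N(0, sd^2/m) noise; regressing the known densities
  # on the observed means, the slope estimator is (to first order) normal
  # with the closed-form OLS standard error.  Coverage of the known-sigma
  # 95% interval over 200 seeded replicates must be at least 95%.
  set.seed(1)
  dens <- c(0, 100, 200, 300)
  slope_true <- 1.5
  inter_true <- 10
  m <- 500          # voxels per rod
  noise_sd <- 5
  hu_true <- slope_true * dens + inter_true
  sd_mean <- noise_sd / sqrt(m)
  # closed-form SE of the fitted density-on-HU slope
  b_true <- 1 / slope_true
  se_b <- (sd_mean / slope_true) / sqrt(sum((hu_true - mean(hu_true))^2))
  dims <- c(20, 10, 10)  # 4 rods of 500 voxels
  masks <- lapply(0:3, function(k) {
    mm <- array(FALSE, dims); mm[k * 5 + 1:5, , ] <- TRUE; mm
  })
  hits <- 0L
  for (r in 1:200) {
    vol <- bos_volume(array(0, dims), c(1, 1, 1), units = "HU")
    for (k in 1:4)
      vol$voxels[masks[[k]]] <- hu_true[k] + rnorm(m, sd = noise_sd)
    fit <- fit_calibration(vol, masks, dens, erode_voxels = 0)
    if (abs(fit$slope_mg_cm3_per_HU - b_true) <= 1.96 * se_b)
      hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})
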