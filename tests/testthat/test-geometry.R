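cal <- small_calibrated()
mask <- segment_femur(cal$volume, rod_masks = cal$gt$rods)

test_that("head sphere fit recovers the known center and radius", {
  head <- find_head_center(mask)
  truth <- femur_head_center(cal$raw$ground_truth$femur)
  expect_lt(max(abs(head$center - truth)), max(mask$spacing))  # within 1 voxel
  expect_lt(abs(head$radius - 15), 1)
})

test_that("a perfect discrete sphere is fitted to sub-voxel accuracy", {
  dims <- c(41, 41, 41)
  vol <- bos_volume(array(0, dims), c(1, 1, 1))
  xyz <- bosscore:::voxel_center_grid(vol)
  sph <- array((xyz[, 1] - 20)^2 + (xyz[, 2] - 20)^2 + (xyz[, 3] - 20)^2 <=
                 15^2, dims)
  surf <- bosscore:::mask_surface_voxels(sph)
  svol <- vol; svol$voxels <- surf
  fit <- fit_sphere(bosscore:::mask_world_coords(svol))
  expect_lt(max(abs(fit$center - c(20, 20, 20))), 0.5)
  # surface voxel centers sit just inside the nominal radius
  expect_lt(abs(fit$radius - 15), 0.5)
})

test_that("a pure cylinder has no spherical head", {
  dims <- c(21, 21, 60)
  vol <- bos_volume(array(0, dims), c(1, 1, 1))
  xyz <- bosscore:::voxel_center_grid(vol)
  cyl <- array((xyz[, 1] - 10)^2 + (xyz[, 2] - 10)^2 <= 8^2, dims)
  cvol <- vol; cvol$voxels <- cyl
  class(cvol) <- c("bos_mask", class(cvol))
  expect_error(find_head_center(cvol), "no spherical head")
})

test_that("an already-aligned femur needs no rotation", {
  head <- find_head_center(mask)
  knee <- find_knee_center(mask, head$center)
  # synthetic shaft axis is z, head on top: knee is near the shaft origin
  expect_lt(sqrt(sum((knee - c(0, 0, 2.5))^2)), 6)
  al <- align_and_crop(cal$volume, mask, head$center, knee)
  axis_angle <- acos(min(1, (sum(diag(al$rotation)) - 1) / 2))
  expect_lt(axis_angle, 0.35)  # head offset tilts the anatomical axis a bit
})

test_that("a known rotation of the scene is inverted by alignment", {
  Q <- rotation_y(30)
  cal_rot <- small_calibrated(rotation = Q)
  mask_rot <- segment_femur(cal_rot$volume, rod_masks = cal_rot$gt$rods)
  head <- find_head_center(mask_rot)
  knee <- find_knee_center(mask_rot, head$center)
  al <- align_and_crop(cal_rot$volume, mask_rot, head$center, knee,
                       crop = FALSE)
  # the recovered head-knee axis, mapped back through the scene rotation,
  # must match the unrotated anatomical axis
  cal0 <- small_calibrated()
  mask0 <- segment_femur(cal0$volume, rod_masks = cal0$gt$rods)
  h0 <- find_head_center(mask0)
  k0 <- find_knee_center(mask0, h0$center)
  ax0 <- (k0 - h0$center) / sqrt(sum((k0 - h0$center)^2))
  axr <- (knee - head$center) / sqrt(sum((knee - head$center)^2))
  expect_lt(max(abs(Q %*% ax0 - axr)), 0.05)
  # and the aligned mask of the rotated scene matches the aligned unrotated one
  al0 <- align_and_crop(cal0$volume, mask0, h0$center, k0, crop = FALSE)
  expect_lt(abs(mask_volume_mm3(al$mask) - mask_volume_mm3(al0$mask)) /
              mask_volume_mm3(al0$mask), 0.03)
})

test_that("alignment conserves density mass within 2%", {
  # phantom-free identity-mapped scene so the whole-grid integrals compare
  # bone mass only
  v <- generate_phantom_volume(small_femur_spec(), phantom = NULL,
                               spacing_mm = c(2, 2, 2))
  v$units <- "mg/cm^3"
  mask_np <- segment_femur(v)
  head <- find_head_center(mask_np)
  knee <- find_knee_center(mask_np, head$center)
  al <- align_and_crop(v, mask_np, head$center, knee,
                       crop = FALSE, margin_mm = 5)
  m_src <- sum(v$voxels) * prod(v$spacing)
  m_dst <- sum(al$volume$voxels) * prod(al$volume$spacing)
  expect_lt(abs(m_dst - m_src) / m_src, 0.02)
})

test_that("cropping keeps the head and respects a distal lesion", {
  head <- find_head_center(mask)
  knee <- find_knee_center(mask, head$center)
  al <- align_and_crop(cal$volume, mask, head$center, knee)
  # head center voxels survive the crop
  expect_true(al$crop_plane_z < 0)
  hc_idx <- round(world_to_voxel(al$mask, rbind(c(0, 0, 0))))
  expect_true(al$mask$voxels[hc_idx[1], hc_idx[2], hc_idx[3]])
  # a lesion below the mid-plane pushes the crop distal to its lowest point
  L <- sqrt(sum((knee - head$center)^2))
  lesion_pts <- rbind(c(0, 0, -0.8 * L), c(0, 0, -0.7 * L))
  al2 <- align_and_crop(cal$volume, mask, head$center, knee,
                        lesion_points = sweep(lesion_pts %*% al$rotation, 2,
                                              -head$center))
  expect_lt(al2$crop_plane_z, -0.8 * L)
})

test_that("coincident centers are rejected", {
  expect_error(align_and_crop(cal$volume, mask, c(0, 0, 0), c(0, 0, 0)),
               "coincide")
})
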