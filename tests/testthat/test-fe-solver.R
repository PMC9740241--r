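single_tet_mesh <- function() {
  structure(list(
    nodes = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    elements = matrix(1:4, nrow = 1),
    element_density_mg_cm3 = 300, cell_mm = c(1, 1, 1),
    volumes_mm3 = 1 / 6), class = "tet_mesh")
}

test_that("single-tet stiffness is symmetric with a 6-dim rigid null space", {
  mesh <- single_tet_mesh()
  K <- as.matrix(assemble_stiffness(mesh, uniform_materials(mesh, E = 1000,
                                                            nu = 0.3)))
  expect_equal(K, t(K), tolerance = 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6L)
  expect_true(all(ev > -1e-8 * max(ev)))
})

test_that("patch test: affine boundary displacements give constant stress", {
  mesh <- voxels_to_tets(box_aligned(3, 3, 3))
  mats <- uniform_materials(mesh, E = 2000, nu = 0.3)
  A <- matrix(c(1e-3, 2e-4, -1e-4,
                3e-4, -5e-4, 2e-4,
                -2e-4, 1e-4, 8e-4), 3, 3, byrow = TRUE)
  surf_nodes <- sort(unique(as.vector(surface_faces(mesh))))
  ub <- mesh$nodes[surf_nodes, ] %*% t(A)
  dofs <- bosscore:::node_dofs(surf_nodes)
  u <- linear_solve(mesh, mats, dofs, as.vector(t(ub)))
  # the interior solution must reproduce the affine field ...
  u_exact <- as.vector(t(mesh$nodes %*% t(A)))
  expect_equal(u, u_exact, tolerance = 1e-10)
  # ... and stresses are constant across elements to machine precision
  sig <- element_stresses(mesh, mats, u)
  expect_lt(max(apply(sig, 2, function(s) diff(range(s)))),
            1e-9 * max(abs(sig)))
})

test_that("strain energy of a uniaxial stretch matches the closed form", {
  mesh <- voxels_to_tets(box_aligned(1, 1, 10))
  mats <- uniform_materials(mesh, E = 1000, nu = 0)
  delta <- 0.02
  u <- numeric(3 * nrow(mesh$nodes))
  u[seq(3, length(u), by = 3)] <- (mesh$nodes[, 3] - min(mesh$nodes[, 3])) /
    10 * delta
  K <- assemble_stiffness(mesh, mats)
  energy <- 0.5 * sum(u * as.numeric(K %*% u))
  expect_equal(energy, 0.5 * 1000 * 1 * delta^2 / 10, tolerance = 1e-10)
})

test_that("elastic bar reaction matches E*A*delta/L", {
  mesh <- voxels_to_tets(box_aligned(1, 1, 10))
  mats <- uniform_materials(mesh, E = 1000, nu = 0)
  lc <- load_case(z_plane_nodes(mesh, TRUE), z_plane_nodes(mesh, FALSE),
                  displacement_increment_mm = 0.01,
                  max_displacement_mm = 0.01)
  sim <- solve_to_failure(mesh, mats, lc)
  expect_equal(sim$F_max_N, 1000 * 1 * 0.01 / 10, tolerance = 1e-8)
  expect_equal(sim$curve$force_N[1], 0)
  expect_equal(sim$F_max_N, max(sim$curve$force_N))
})

test_that("elastic response is linear in the prescribed displacement", {
  mesh <- voxels_to_tets(box_aligned(2, 2, 6))
  mats <- uniform_materials(mesh, E = 500, nu = 0.3)
  run <- function(d) solve_to_failure(mesh, mats,
    load_case(z_plane_nodes(mesh, TRUE), z_plane_nodes(mesh, FALSE),
              displacement_increment_mm = d, max_displacement_mm = d))$F_max_N
  f1 <- run(0.02)
  f2 <- run(0.01)
  expect_equal(f1 / f2, 2, tolerance = 1e-8)
})

test_that("perfectly plastic bar peaks at the limit load sigma_y * A", {
  mesh <- voxels_to_tets(box_aligned(1, 1, 10))
  mats <- uniform_materials(mesh, E = 1000, nu = 0, sigma_y = 10, H = 0.1)
  lc <- load_case(z_plane_nodes(mesh, TRUE), z_plane_nodes(mesh, FALSE),
                  displacement_increment_mm = 0.05,
                  max_displacement_mm = 0.5)
  sim <- solve_to_failure(mesh, mats, lc)
  expect_equal(sim$F_max_N, 10, tolerance = 0.01)
  expect_gt(length(sim$plastic_elements_at_peak), 0)
  # equilibrium: nodal internal forces sum to zero at the converged peak
  f <- internal_forces(mesh, mats, sim$u_at_peak)
  expect_lt(max(abs(colSums(matrix(f, ncol = 3, byrow = TRUE)))),
            1e-6 * sim$F_max_N)
})

test_that("the response is invariant under rigid pre-translation", {
  mesh <- voxels_to_tets(box_aligned(1, 1, 8))
  mats <- uniform_materials(mesh, E = 800, nu = 0.25, sigma_y = 8, H = 0.05)
  lc <- function(m) load_case(z_plane_nodes(m, TRUE), z_plane_nodes(m, FALSE),
                              displacement_increment_mm = 0.05,
                              max_displacement_mm = 0.3)
  sim1 <- solve_to_failure(mesh, mats, lc(mesh))
  shifted <- mesh
  shifted$nodes <- sweep(mesh$nodes, 2, c(12.3, -4.5, 99), "+")
  sim2 <- solve_to_failure(shifted, mats, lc(shifted))
  expect_equal(sim1$curve, sim2$curve, tolerance = 1e-9)
})

test_that("zero-volume elements are rejected at assembly", {
  mesh <- single_tet_mesh()
  mesh$nodes[4, ] <- c(0.5, 0.5, 0)  # flatten the tet
  expect_error(assemble_stiffness(mesh, uniform_materials(mesh)),
               "zero-volume")
})
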