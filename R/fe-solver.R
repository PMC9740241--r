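#' Assemble the global elastic stiffness matrix
#'
#' Standard linear-tetrahedron assembly, `K = sum_e V_e B_e^T D_e B_e`,
#' returned as a sparse symmetric matrix over all 3N displacement degrees of
#' freedom (node-major x, y, z ordering).
#'
#' @param mesh a `tet_mesh`.
#' @param materials a `material_field` from [map_materials()].
#' @return a `dgCMatrix` of dimension 3N x 3N.
#' @export
assemble_stiffness <- function(mesh, materials) {
  g <- tet_grads_cpp(mesh$nodes, mesh$elements)
  if (any(g$vols <= 0)) stop("mesh contains zero-volume or inverted elements")
  D <- elastic_D_cpp(materials$E_MPa, materials$nu)
  tr <- assemble_triplets_cpp(mesh$elements, g$grads, g$vols, D)
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                       dims = rep(3L * nrow(mesh$nodes), 2))
}

#' Define the stance load case
#'
#' Nodes on the femoral-head surface within a polar cap about the +z pole are
#' displaced uniformly along the load direction; nodes on the distal cut
#' plane are fully fixed.
#'
#' @param mesh a `tet_mesh` in the aligned frame (head at the origin, +z up).
#' @param head_center,head_radius fitted head sphere (aligned frame).
#' @param cap_angle_deg half-angle of the loaded cap (default 30 degrees).
#' @param displacement_increment_mm prescribed displacement step.
#' @param max_displacement_mm ramp limit.
#' @param load_direction unit load direction (default -z).
#' @param stop_force_fraction stop once the force falls below this fraction
#'   of the running maximum (default 0.95).
#' @return a `load_case`.
#' @export
stance_load_case <- function(mesh, head_center = c(0, 0, 0),
                             head_radius = NULL, cap_angle_deg = 30,
                             displacement_increment_mm = 0.05,
                             max_displacement_mm = 1,
                             load_direction = c(0, 0, -1),
                             stop_force_fraction = 0.95) {
  surf_nodes <- sort(unique(as.vector(surface_faces(mesh))))
  rel <- sweep(mesh$nodes[surf_nodes, , drop = FALSE], 2, head_center)
  r <- sqrt(rowSums(rel^2))
  polar <- acos(pmin(1, pmax(-1, rel[, 3] / pmax(r, 1e-12))))
  sel <- polar <= cap_angle_deg * pi / 180
  if (!is.null(head_radius))
    sel <- sel & r >= 0.6 * head_radius  # exclude near-center nodes
  loaded <- surf_nodes[sel]
  zmin <- min(mesh$nodes[, 3])
  fixed <- which(mesh$nodes[, 3] <= zmin + 1e-6 + 1e-3 * min(mesh$cell_mm))
  load_case(loaded, fixed, load_direction, displacement_increment_mm,
            max_displacement_mm, stop_force_fraction)
}

#' @rdname stance_load_case
#' @param loaded_nodes,fixed_nodes node index sets (1-based).
#' @export
load_case <- function(loaded_nodes, fixed_nodes,
                      load_direction = c(0, 0, -1),
                      displacement_increment_mm = 0.05,
                      max_displacement_mm = 1, stop_force_fraction = 0.95) {
  loaded_nodes <- as.integer(loaded_nodes)
  fixed_nodes <- as.integer(fixed_nodes)
  if (length(loaded_nodes) == 0 || length(fixed_nodes) == 0)
    stop("loaded and fixed node sets must be nonempty")
  if (length(intersect(loaded_nodes, fixed_nodes)) > 0)
    stop("loaded and fixed node sets must be disjoint")
  dir <- load_direction / sqrt(sum(load_direction^2))
  structure(list(loaded_nodes = loaded_nodes, fixed_nodes = fixed_nodes,
                 load_direction = dir,
                 displacement_increment_mm = displacement_increment_mm,
                 max_displacement_mm = max_displacement_mm,
                 stop_force_fraction = stop_force_fraction),
            class = "load_case")
}

node_dofs <- function(nodes) as.vector(t(cbind(3 * nodes - 2, 3 * nodes - 1,
                                               3 * nodes)))

#' Displacement-controlled elastoplastic simulation to peak force
#'
#' Ramps a uniform displacement of the loaded nodes along the load direction
#' in increments.  Each increment is equilibrated by Newton iteration with a
#' radial-return von Mises stress update and the algorithmically consistent
#' tangent; non-converged increments are bisected.  The femur's strength is
#' the maximum total reaction force over the ramp; the weakest location is
#' the set of elements with plastic strain at the peak step.
#'
#' @param mesh a `tet_mesh`.
#' @param materials a `material_field`.
#' @param load a `load_case`.
#' @param newton_tol relative residual tolerance (default 1e-6).
#' @param max_iter Newton iterations per increment (default 25).
#' @param plastic_strain_tol equivalent plastic strain above which an element
#'   counts as plastically deformed (default 1e-8).
#' @return a `simulation_result`: `curve` (data frame of displacement and
#'   total reaction force), `F_max_N`, `plastic_elements_at_peak`,
#'   `converged` (per recorded step), `eqpl_at_peak`, `u_at_peak`.
#' @export
solve_to_failure <- function(mesh, materials, load, newton_tol = 1e-6,
                             max_iter = 25L, plastic_strain_tol = 1e-8,
                             verbose = FALSE) {
  stopifnot(inherits(load, "load_case"))
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elements)
  g <- tet_grads_cpp(mesh$nodes, mesh$elements)
  if (any(g$vols <= 0)) stop("mesh contains zero-volume or inverted elements")
  ndof <- 3L * n
  fixed_dofs <- node_dofs(load$fixed_nodes)
  # loaded nodes are displacement-controlled along the load axis only;
  # their transverse components stay free so plastic incompressibility is
  # not artificially confined at the contact patch
  axis <- which.max(abs(load$load_direction))
  if (max(abs(load$load_direction[-axis])) > 1e-9)
    stop("load_direction must be axis-aligned for displacement control")
  sgn <- sign(load$load_direction[axis])
  loaded_dofs <- 3L * (load$loaded_nodes - 1L) + axis
  presc <- c(fixed_dofs, loaded_dofs)
  free <- setdiff(seq_len(ndof), presc)
  u <- numeric(ndof)
  eps_p <- matrix(0, m, 6)
  eqpl <- numeric(m)
  # the triplet pattern is fixed by the mesh: precompute the free-free block
  # selection and reuse the symbolic Cholesky factorization across iterations
  dof_map <- integer(ndof)
  dof_map[free] <- seq_along(free)
  tr0 <- assemble_triplets_cpp(mesh$elements, g$grads, g$vols,
                               elastic_D_cpp(materials$E_MPa, materials$nu))
  keep_ff <- dof_map[tr0$i] > 0L & dof_map[tr0$j] > 0L
  ri <- dof_map[tr0$i[keep_ff]]
  rj <- dof_map[tr0$j[keep_ff]]
  nfree <- length(free)
  chol_sym <- NULL
  solve_ff <- function(x_vals, rhs) {
    Kff <- Matrix::forceSymmetric(Matrix::sparseMatrix(
      i = ri, j = rj, x = x_vals, dims = c(nfree, nfree)))
    if (is.null(chol_sym)) {
      chol_sym <<- Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE)
      return(as.numeric(Matrix::solve(chol_sym, rhs)))
    }
    f <- tryCatch(Matrix::update(chol_sym, Kff), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    as.numeric(Matrix::solve(f, rhs))
  }
  curve <- data.frame(displacement_mm = 0, force_N = 0)
  converged <- TRUE
  F_max <- 0
  eqpl_peak <- eqpl
  u_peak <- u
  d_done <- 0
  inc <- load$displacement_increment_mm
  inc_floor <- inc / 64
  easy_streak <- 0L
  while (d_done < load$max_displacement_mm - 1e-12) {
    step <- min(inc, load$max_displacement_mm - d_done)
    d_try <- d_done + step
    u_try <- u
    u_try[fixed_dofs] <- 0
    u_try[loaded_dofs] <- d_try * sgn
    ok <- FALSE
    iters_used <- 0L
    upd <- state_update_cpp(u_try, mesh$elements, g$grads, g$vols,
                            materials$E_MPa, materials$nu,
                            materials$sigma_y_MPa, materials$H_MPa,
                            eps_p, eqpl)
    rn <- sqrt(sum(upd$fint[free]^2))
    for (it in seq_len(max_iter)) {
      iters_used <- it
      ref <- max(sqrt(sum(upd$fint[presc]^2)), 1e-8)
      if (rn <= newton_tol * ref) {
        ok <- TRUE
        break
      }
      tr <- assemble_triplets_cpp(mesh$elements, g$grads, g$vols, upd$D)
      du <- tryCatch(solve_ff(tr$x[keep_ff], -upd$fint[free]),
                     error = function(e) NULL)
      if (is.null(du)) break
      # backtracking line search on the residual norm: plastic/elastic state
      # switching makes the full Newton step overshoot near the limit load
      alpha <- 1
      for (ls in 1:5) {
        u_cand <- u_try
        u_cand[free] <- u_try[free] + alpha * du
        upd_cand <- state_update_cpp(u_cand, mesh$elements, g$grads, g$vols,
                                     materials$E_MPa, materials$nu,
                                     materials$sigma_y_MPa, materials$H_MPa,
                                     eps_p, eqpl)
        rn_cand <- sqrt(sum(upd_cand$fint[free]^2))
        if (rn_cand < rn || ls == 5) break
        alpha <- alpha / 2
      }
      u_try <- u_cand
      upd <- upd_cand
      rn <- rn_cand
    }
    if (verbose)
      message(sprintf("step d=%.4f inc=%.4f iters=%d ok=%s", d_try, step,
                      iters_used, ok))
    if (!ok) {
      inc <- inc / 2
      if (inc < inc_floor)
        stop("solver diverged: increment fell below the bisection floor")
      next
    }
    # commit converged state; recover the increment only after a streak of
    # easy steps, so a persistently hard step size is not retried every time
    if (iters_used <= max_iter %/% 3) {
      easy_streak <- easy_streak + 1L
      if (easy_streak >= 3L && inc < load$displacement_increment_mm) {
        inc <- min(2 * inc, load$displacement_increment_mm)
        easy_streak <- 0L
      }
    } else easy_streak <- 0L
    u <- u_try
    eps_p <- upd$eps_p
    eqpl <- upd$eqpl
    d_done <- d_try
    F_tot <- sgn * sum(upd$fint[loaded_dofs])
    curve <- rbind(curve, data.frame(displacement_mm = d_done,
                                     force_N = F_tot))
    converged <- c(converged, TRUE)
    if (F_tot > F_max) {
      F_max <- F_tot
      eqpl_peak <- eqpl
      u_peak <- u
    }
    if (F_max > 0 && F_tot < load$stop_force_fraction * F_max) break
  }
  structure(list(curve = curve, F_max_N = F_max,
                 plastic_elements_at_peak = which(eqpl_peak >
                                                    plastic_strain_tol),
                 converged = converged, eqpl_at_peak = eqpl_peak,
                 u_at_peak = u_peak, load = load),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> F_max = %.2f N at %.3f mm; %d plastic elements; %d steps\n",
    x$F_max_N, x$curve$displacement_mm[which.max(x$curve$force_N)],
    length(x$plastic_elements_at_peak), nrow(x$curve) - 1))
  invisible(x)
}

#' Linear elastic solve under prescribed displacements
#'
#' Single linear solve used by verification tests (patch test, energy
#' checks): displacement boundary conditions on selected degrees of freedom,
#' zero external force elsewhere.
#'
#' @param mesh a `tet_mesh`.
#' @param materials a `material_field`.
#' @param prescribed_dofs integer DOF indices (node-major x,y,z).
#' @param prescribed_values their displacement values (mm).
#' @return full displacement vector of length 3N.
#' @export
linear_solve <- function(mesh, materials, prescribed_dofs, prescribed_values) {
  K <- assemble_stiffness(mesh, materials)
  ndof <- nrow(K)
  u <- numeric(ndof)
  u[prescribed_dofs] <- prescribed_values
  free <- setdiff(seq_len(ndof), prescribed_dofs)
  rhs <- -K[free, prescribed_dofs, drop = FALSE] %*% u[prescribed_dofs]
  u[free] <- as.numeric(Matrix::solve(Matrix::forceSymmetric(
    K[free, free, drop = FALSE]), rhs))
  u
}

#' Element stresses for a given displacement field
#'
#' @param mesh a `tet_mesh`.
#' @param materials a `material_field`.
#' @param u displacement vector of length 3N.
#' @return m x 6 matrix of Voigt stresses (xx, yy, zz, xy, yz, zx), MPa.
#' @export
element_stresses <- function(mesh, materials, u) {
  g <- tet_grads_cpp(mesh$nodes, mesh$elements)
  m <- nrow(mesh$elements)
  upd <- state_update_cpp(u, mesh$elements, g$grads, g$vols, materials$E_MPa,
                          materials$nu, rep(Inf, m), materials$H_MPa,
                          matrix(0, m, 6), numeric(m))
  upd$sigma
}

#' Internal nodal forces for a displacement field
#' @inheritParams element_stresses
#' @return numeric vector of length 3N.
#' @export
internal_forces <- function(mesh, materials, u) {
  g <- tet_grads_cpp(mesh$nodes, mesh$elements)
  m <- nrow(mesh$elements)
  upd <- state_update_cpp(u, mesh$elements, g$grads, g$vols, materials$E_MPa,
                          materials$nu, materials$sigma_y_MPa,
                          materials$H_MPa, matrix(0, m, 6), numeric(m))
  upd$fint
}
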