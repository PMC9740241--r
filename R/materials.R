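#' Density-to-material power law
#'
#' Maps calcium-equivalent density to an isotropic elastoplastic material:
#' Young's modulus `E = a * rho^b` (MPa, rho in g/cm^3) and von Mises yield
#' stress `sigma_y = c * rho^d` (MPa), both floored to keep the stiffness
#' matrix positive definite at zero density.  The default constants are
#' implementation choices in the range of published trabecular/cortical
#' density-modulus and density-strength fits, not values prescribed by any
#' single source; they are fully configurable.
#'
#' A small linear hardening modulus `H = hardening_ratio * E` regularizes the
#' perfectly plastic limit (a vanishing tangent makes the Newton system
#' singular at the limit load); at the default ratio its effect on the peak
#' force is far below the reported precision.
#'
#' @param modulus_coeff_MPa,modulus_exponent modulus law `a`, `b`.
#' @param yield_coeff_MPa,yield_exponent yield law `c`, `d`.
#' @param poisson_ratio Poisson's ratio (default 0.3).
#' @param E_min_MPa,sigma_min_MPa property floors (defaults 1 and 0.1 MPa).
#' @param hardening_ratio H / E (default 1e-4; 0 gives perfect plasticity).
#' @return object of class `material_law`.
#' @export
material_law <- function(modulus_coeff_MPa = 6850, modulus_exponent = 1.49,
                         yield_coeff_MPa = 38.5, yield_exponent = 2,
                         poisson_ratio = 0.3, E_min_MPa = 1,
                         sigma_min_MPa = 0.1, hardening_ratio = 1e-4) {
  if (modulus_coeff_MPa < 0 || yield_coeff_MPa < 0 ||
      modulus_exponent < 0 || yield_exponent < 0)
    stop("material law coefficients and exponents must be >= 0")
  if (E_min_MPa <= 0 || sigma_min_MPa <= 0)
    stop("property floors must be strictly positive")
  if (poisson_ratio <= -1 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in (-1, 0.5)")
  structure(list(modulus_coeff_MPa = modulus_coeff_MPa,
                 modulus_exponent = modulus_exponent,
                 yield_coeff_MPa = yield_coeff_MPa,
                 yield_exponent = yield_exponent,
                 poisson_ratio = poisson_ratio, E_min_MPa = E_min_MPa,
                 sigma_min_MPa = sigma_min_MPa,
                 hardening_ratio = hardening_ratio),
            class = "material_law")
}

#' Map element densities to material properties
#'
#' @param mesh a `tet_mesh` with per-element densities (mg/cm^3).
#' @param law a [material_law].
#' @return a `material_field`: list of per-element vectors `E_MPa`,
#'   `sigma_y_MPa`, `H_MPa` and scalar-recycled `nu`.
#' @export
map_materials <- function(mesh, law = material_law()) {
  rho <- mesh$element_density_mg_cm3 / 1000  # g/cm^3
  if (any(rho < 0)) stop("element densities must be >= 0")
  E <- pmax(law$modulus_coeff_MPa * rho^law$modulus_exponent, law$E_min_MPa)
  sy <- pmax(law$yield_coeff_MPa * rho^law$yield_exponent, law$sigma_min_MPa)
  m <- length(rho)
  structure(list(E_MPa = E, sigma_y_MPa = sy,
                 nu = rep(law$poisson_ratio, m),
                 H_MPa = law$hardening_ratio * E, law = law),
            class = "material_field")
}
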