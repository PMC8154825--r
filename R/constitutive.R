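# Density-dependent material laws and their plane-problem reduction.
#
# Unit system: mm - N - MPa - day - V - C, densities in g/cm^3.
# With these units 1 MPa = 1 J/cm^3, so U/rho (SED per density) carries
# J/g and is directly comparable with the reference stimulus S_r.

#' Material parameters for bone remodelling simulations
#'
#' Bundles the constitutive constants of the density-dependent elastic law,
#' the remodelling rate law, the side-plate elasticity, and the piezoelectric
#' and dielectric tensors of bone.  Defaults are the values commonly used for
#' strain-adaptive remodelling of the proximal femur (Weinans-type power law
#' with \eqn{E(\rho) = M\rho^\gamma}) together with hexagonal-symmetry
#' piezoelectric constants for cortical bone.
#'
#' @param rho_min Minimal apparent density \eqn{\rho_a} (g/cm^3), the fully
#'   resorbed limit.  Default 0.010.
#' @param rho_max Maximal apparent density \eqn{\rho_b} (g/cm^3), cortical
#'   bone.  Default 1.740.
#' @param S_r Reference stimulus (J/g): the SED-per-density set point at which
#'   remodelling is in equilibrium.  Default 0.004.
#' @param B Remodelling rate constant ((g cm^-3)^2 (MPa day)^-1).  Default 1.
#' @param M Constitutive constant of the power law (MPa/(cm^3/g)^gamma).
#'   Default 3790.
#' @param gamma Power-law exponent (dimensionless).  Default 3.
#' @param k Poisson's ratio of bone, assumed density-independent.  Default 0.3.
#' @param plate_E Elastic modulus of the non-remodelling side-plate (MPa).
#'   Default 17000.
#' @param plate_k Poisson's ratio of the side-plate.  Default 0.3.
#' @param e31,e33,e15 Piezoelectric stress coefficients (C/mm^2).
#' @param e14 Piezoelectric coefficient coupling out-of-plane shear only; it
#'   is inert in the plane problem and defaults to 0.
#' @param beta11,beta33 Electric permittivity coefficients (F/mm).
#' @param lame_convention `"remodelling"` uses \eqn{\lambda = kE/(1-k^2)} (the form
#'   used by the remodelling literature this model follows, which makes a bar
#'   under uniaxial in-plane stress obey \eqn{\epsilon = \sigma/E} exactly);
#'   `"standard"` uses the 3-D \eqn{\lambda = kE/((1+k)(1-2k))}.
#' @param stimulus `"full_stress"` evaluates the SED stimulus with the full
#'   piezoelectric stress (including the converse-effect term); or
#'   `"mechanical_only"` with the purely elastic stress.
#'
#' @return An object of class `material_params` (a validated list).
#' @examples
#' p <- material_params()
#' elastic_modulus(1.0, p)   # 3790 MPa
#' @export
material_params <- function(rho_min = 0.010, rho_max = 1.740,
                            S_r = 0.004, B = 1,
                            M = 3790, gamma = 3, k = 0.3,
                            plate_E = 17000, plate_k = 0.3,
                            e31 = 1.50765e-9, e33 = 1.87209e-9,
                            e15 = 3.57643e-9, e14 = 0,
                            beta11 = 88.54e-12, beta33 = 106.248e-12,
                            lame_convention = c("remodelling", "standard"),
                            stimulus = c("full_stress", "mechanical_only")) {
  p <- list(
    rho_min = rho_min, rho_max = rho_max, S_r = S_r, B = B,
    M = M, gamma = gamma, k = k,
    plate_E = plate_E, plate_k = plate_k,
    e31 = e31, e33 = e33, e15 = e15, e14 = e14,
    beta11 = beta11, beta33 = beta33,
    lame_convention = match.arg(lame_convention),
    stimulus = match.arg(stimulus)
  )
  num <- c("rho_min", "rho_max", "S_r", "B", "M", "gamma", "k",
           "plate_E", "plate_k", "e31", "e33", "e15", "e14",
           "beta11", "beta33")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("material parameter '", nm, "' must be a finite numeric scalar")
  }
  if (p$rho_min <= 0 || p$rho_min >= p$rho_max)
    stop("material parameters require 0 < rho_min < rho_max")
  if (p$M <= 0) stop("M must be > 0")
  if (p$gamma <= 0) stop("gamma must be > 0")
  if (p$k < 0 || p$k >= 0.5) stop("Poisson's ratio k must satisfy 0 <= k < 0.5")
  if (p$plate_k < 0 || p$plate_k >= 0.5) stop("plate_k must satisfy 0 <= k < 0.5")
  if (p$beta11 <= 0 || p$beta33 <= 0) stop("permittivities must be > 0")
  structure(p, class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("<material_params>\n")
  cat(sprintf("  density bounds: [%g, %g] g/cm^3; S_r = %g J/g; B = %g\n",
              x$rho_min, x$rho_max, x$S_r, x$B))
  cat(sprintf("  E(rho) = %g * rho^%g MPa (k = %g, lambda convention '%s')\n",
              x$M, x$gamma, x$k, x$lame_convention))
  cat(sprintf("  side-plate: E = %g MPa, k = %g\n", x$plate_E, x$plate_k))
  cat(sprintf("  piezo e31/e33/e15 = %.4g/%.4g/%.4g C/mm^2; beta11/beta33 = %.4g/%.4g F/mm\n",
              x$e31, x$e33, x$e15, x$beta11, x$beta33))
  invisible(x)
}

#' Override fields of a material parameter set
#'
#' @param params A [material_params()] object.
#' @param ... Named fields to replace (same names as [material_params()]).
#' @return A revalidated `material_params` object.
#' @export
update_material_params <- function(params, ...) {
  stopifnot(inherits(params, "material_params"))
  upd <- list(...)
  bad <- setdiff(names(upd), names(unclass(params)))
  if (length(bad)) stop("unknown material parameter(s): ", paste(bad, collapse = ", "))
  args <- utils::modifyList(unclass(params), upd)
  do.call(material_params, args)
}

check_density_bounds <- function(rho, params, what = "rho") {
  if (any(!is.finite(rho)))
    stop(what, " contains non-finite values")
  if (any(rho < params$rho_min - 1e-12) || any(rho > params$rho_max + 1e-12))
    stop(what, " outside the admissible density range [",
         params$rho_min, ", ", params$rho_max, "] g/cm^3")
  invisible(rho)
}

#' Density-dependent elastic modulus
#'
#' Power law \eqn{E(\rho) = M \rho^\gamma}.
#'
#' @param rho Apparent density (g/cm^3), scalar or vector, within
#'   `[rho_min, rho_max]`.
#' @param params A [material_params()] object.
#' @return Elastic modulus in MPa (vectorised over `rho`).
#' @examples
#' elastic_modulus(0.8, material_params())  # 3790 * 0.8^3 = 1940.48
#' @export
elastic_modulus <- function(rho, params = material_params()) {
  check_density_bounds(rho, params)
  params$M * rho^params$gamma
}

#' Lame coefficients of the density-dependent elastic law
#'
#' \eqn{\mu = E/(2(1+k))} and, under the default convention,
#' \eqn{\lambda = kE/(1-k^2)}.
#'
#' @inheritParams elastic_modulus
#' @param E Optional elastic modulus (MPa); computed from `rho` when `NULL`.
#'   Supplying `E` with `k` from `params` is used for the side-plate.
#' @param k Optional Poisson's ratio override.
#' @return List with components `mu` and `lambda` (MPa), vectorised.
#' @export
lame_coefficients <- function(rho, params = material_params(),
                              E = NULL, k = NULL) {
  if (is.null(E)) E <- elastic_modulus(rho, params)
  if (is.null(k)) k <- params$k
  mu <- E / (2 * (1 + k))
  lambda <- switch(params$lame_convention,
    remodelling = k * E / (1 - k^2),
    standard = k * E / ((1 + k) * (1 - 2 * k))
  )
  list(mu = mu, lambda = lambda)
}

#' Density scaling of the piezoelectric and dielectric tensors
#'
#' \eqn{\alpha(\rho) = \rho^\gamma}, the dimensionless factor scaling the
#' coupling and permittivity tensors with apparent density.
#'
#' @inheritParams elastic_modulus
#' @return Dimensionless scale (vectorised).
#' @export
alpha_coupling <- function(rho, params = material_params()) {
  check_density_bounds(rho, params)
  rho^params$gamma
}

# Plane elasticity matrix (Voigt order exx, eyy, gxy) for E = 1.
# Multiplying by E(rho) gives C(rho); valid because k is density-independent.
plane_elastic_unit <- function(k, convention = "remodelling") {
  mu <- 1 / (2 * (1 + k))
  lambda <- if (convention == "remodelling") k / (1 - k^2) else k / ((1 + k) * (1 - 2 * k))
  matrix(c(lambda + 2 * mu, lambda, 0,
           lambda, lambda + 2 * mu, 0,
           0, 0, mu), 3, 3, byrow = TRUE)
}

# Vacuum permittivity in F/mm, used for the electrically passive side-plate
# so the potential problem stays well-posed over the whole domain.
EPS0_F_PER_MM <- 8.8541878128e-15

#' Plane-problem constitutive tensors
#'
#' Reduces the full hexagonal-symmetry constitutive law to the working plane.
#' The material 3-axis (the poling / longitudinal axis of the femur) is
#' aligned with the global vertical (y) axis of the 2-D model and the
#' material 1-axis with the horizontal (x) axis; the out-of-plane direction
#' is the material 2-axis.  Under plane-strain kinematics
#' (\eqn{\epsilon_{22}=\gamma_{12}=\gamma_{23}=0}, \eqn{E_2=0}) the `e14`
#' terms vanish identically and the remaining coupling is carried by
#' `e31`, `e33` (vertical field) and `e15` (horizontal field).
#'
#' @inheritParams elastic_modulus
#' @param region `"FEMUR"` (density-dependent, piezoelectrically active) or
#'   `"SIDE_PLATE"` (constant elasticity, no coupling, vacuum-scale
#'   permittivity).
#' @return A list of class `plane_tensors` with
#'   \describe{
#'     \item{C}{3x3 elasticity matrix (MPa), Voigt order (exx, eyy, gxy).}
#'     \item{e2d}{2x3 coupling matrix (C/mm^2); row 1 acts on the horizontal
#'       electric field component, row 2 on the vertical one.}
#'     \item{beta2d}{2x2 permittivity matrix (F/mm), diag(beta11, beta33)
#'       scaled by \eqn{\alpha(\rho)} for bone.}
#'   }
#' @export
plane_tensors <- function(rho, params = material_params(),
                          region = c("FEMUR", "SIDE_PLATE")) {
  region <- match.arg(region)
  if (region == "SIDE_PLATE") {
    C <- params$plate_E * plane_elastic_unit(params$plate_k, params$lame_convention)
    e2d <- matrix(0, 2, 3)
    beta2d <- diag(c(EPS0_F_PER_MM, EPS0_F_PER_MM))
  } else {
    a <- alpha_coupling(rho, params)
    C <- elastic_modulus(rho, params) *
      plane_elastic_unit(params$k, params$lame_convention)
    e2d <- a * rbind(c(0, 0, params$e15),
                     c(params$e31, params$e33, 0))
    beta2d <- a * diag(c(params$beta11, params$beta33))
  }
  structure(list(C = C, e2d = e2d, beta2d = beta2d, region = region),
            class = "plane_tensors")
}

#' Full hexagonal-symmetry piezoelectric tensor (3x6 Voigt) and permittivity
#'
#' The unreduced 3-D tensors; mainly useful as an independent oracle for the
#' plane reduction performed by [plane_tensors()].  Voigt column order is
#' (11, 22, 33, 23, 13, 12) in material axes, rows are the electric axes.
#'
#' @param params A [material_params()] object.
#' @return List with `e3d` (3x6, C/mm^2) and `beta3d` (3x3, F/mm), unscaled
#'   by \eqn{\alpha(\rho)}.
#' @export
piezo_tensors_3d <- function(params = material_params()) {
  e3d <- matrix(0, 3, 6)
  e3d[1, 4] <- params$e14
  e3d[1, 5] <- params$e15
  e3d[2, 4] <- params$e15
  e3d[2, 5] <- -params$e14
  e3d[3, 1] <- params$e31
  e3d[3, 2] <- params$e31
  e3d[3, 3] <- params$e33
  beta3d <- diag(c(params$beta11, params$beta11, params$beta33))
  list(e3d = e3d, beta3d = beta3d)
}
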