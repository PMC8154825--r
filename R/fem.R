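# Element-level and global assembly of the elastic and coupled
# piezoelectric systems, boundary conditions, and quasi-static solves.
#
# Discretisation: 3-node linear triangles for displacement and potential
# (constant strain / constant field per element), pairing naturally with
# the elementwise-constant density of the remodelling law.  Voigt order
# (exx, eyy, gxy) with engineering shear.  The coupled system is the
# unsymmetric-saddle arrangement
#     [ K_uu   K_uphi ] [u  ]   [f]
#     [-K_phiu K_phiphi] [phi] = [q]
# with K_phiu = t(K_uphi), solved by one sparse LU factorisation.

# Geometry of one linear triangle: area, strain-displacement matrix B
# (3 x 6) and scalar-gradient matrix G (2 x 3).
tri_geometry <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2])
  cc <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1])
  area2 <- x[1] * b[1] + x[2] * b[2] + x[3] * b[3]
  area <- area2 / 2
  B <- matrix(0, 3, 6)
  B[1, c(1, 3, 5)] <- b
  B[2, c(2, 4, 6)] <- cc
  B[3, c(1, 3, 5)] <- cc
  B[3, c(2, 4, 6)] <- b
  B <- B / area2
  G <- rbind(b, cc) / area2
  list(area = area, B = B, G = G)
}

#' Local stiffness matrix of a linear triangle
#'
#' \eqn{K_e = A\, t\, B^T C B} for the constant-strain triangle: exact
#' quadrature since the integrand is constant over the element.
#'
#' @param coords 3 x 2 matrix of node coordinates (mm), counter-clockwise.
#' @param C 3 x 3 plane elasticity matrix (MPa), Voigt order
#'   (exx, eyy, gxy).
#' @param thickness Out-of-plane thickness (mm).
#' @return Symmetric 6 x 6 stiffness matrix (dof order u1x, u1y, ..., u3y).
#' @export
element_stiffness <- function(coords, C, thickness = 1) {
  g <- tri_geometry(as.matrix(coords))
  if (!is.finite(g$area) || abs(g$area) < .Machine$double.eps * 100)
    stop("degenerate element: zero area")
  if (g$area < 0)
    stop("element has negative area (clockwise node order)")
  g$area * thickness * crossprod(g$B, C %*% g$B)
}

#' Boundary condition sets for a quasi-static solve
#'
#' Collects the constrained node sets of the model: the resection plane at
#' the bottom restrained vertically, the short lower lateral edge (T-R)
#' restrained in both directions to remove rigid-body modes, and (for the
#' coupled model) the electrically grounded chain.
#'
#' @param mesh A [bone_mesh()].
#' @param fixed_vertical Segment name or node ids restrained in y.
#' @param fixed_both Segment name or node ids restrained in x and y.
#' @param grounded Segment name or node ids with potential fixed to 0
#'   (required for a piezoelectric solve).
#' @param head_segment,trochanter_segment,charge_segment Default segments
#'   used by the gait load cases and the stimulation charge.
#' @return Object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(mesh,
                                fixed_vertical = "BOTTOM_EDGE",
                                fixed_both = "LEFT_EDGE",
                                grounded = "LEFT_EDGE",
                                head_segment = "HEAD_ARC",
                                trochanter_segment = "TROCHANTER_ARC",
                                charge_segment = "TROCHANTER_ARC") {
  res <- function(x) if (is.null(x)) integer() else resolve_segment(mesh, x)
  structure(list(fixed_vertical = res(fixed_vertical),
                 fixed_both = res(fixed_both),
                 grounded = res(grounded),
                 head_segment = head_segment,
                 trochanter_segment = trochanter_segment,
                 charge_segment = charge_segment),
            class = "boundary_conditions")
}

# Direction of a traction at `angle` degrees from the global vertical.
# sense "down": load points downward (into the femoral head), positive
# angles rotate the vector toward +x (medial).  sense "up": reaction points
# upward (into the trochanter), positive angles rotate toward -x, so the
# two senses oppose each other at equal angles.
traction_direction <- function(angle, sense = c("down", "up")) {
  sense <- match.arg(sense)
  a <- angle * pi / 180
  if (sense == "down") c(sin(a), -cos(a)) else c(-sin(a), cos(a))
}

#' Consistent nodal loads of a parabolic boundary traction
#'
#' Distributes a total force over an ordered boundary chain with a traction
#' magnitude varying parabolically along the arc length (zero at both chain
#' ends, maximum at mid-arc) and a uniform direction at `angle` degrees from
#' the vertical.  The assembled nodal loads are consistent (linear shape
#' functions, exact Gauss integration) and their resultant equals
#' `total_force` in magnitude and direction by construction.
#'
#' @param mesh A [bone_mesh()].
#' @param segment Boundary segment name or ordered node id chain
#'   (at least 3 nodes).
#' @param total_force Resultant force magnitude (N), > 0.
#' @param angle Angle from the global vertical axis (degrees), |angle| <= 90.
#' @param sense `"down"` (femoral head load) or `"up"` (abductor reaction on
#'   the trochanter).
#' @param thickness Slice thickness (mm); defaults to the thickness of the
#'   region touching the segment's first element.
#' @return Global load vector of length `2 * n_nodes` (N).
#' @export
parabolic_traction_vector <- function(mesh, segment, total_force, angle,
                                      sense = "down", thickness = NULL) {
  chain <- resolve_segment(mesh, segment)
  if (length(chain) < 3L)
    stop("parabolic traction needs a segment of at least 3 nodes")
  if (total_force <= 0) stop("total_force must be > 0")
  if (abs(angle) > 90) stop("|angle| must be <= 90 degrees")
  if (is.null(thickness)) thickness <- mesh$thickness[["FEMUR"]]
  arc <- chain_arclength(mesh, chain)
  L <- arc$total
  if (L <= 0) stop("segment has zero length")
  d <- traction_direction(angle, sense)
  # t(s) = tmax * 4 s (L - s) / L^2 ; integral over the chain = tmax * 2L/3
  tmax <- 3 * total_force / (2 * L * thickness)
  shape <- function(s) tmax * 4 * s * (L - s) / L^2
  nodal <- numeric(length(chain))
  gp <- c(0.5 - 0.5 / sqrt(3), 0.5 + 0.5 / sqrt(3))
  for (k in seq_len(length(chain) - 1L)) {
    le <- arc$s[k + 1L] - arc$s[k]
    for (xi in gp) {
      tv <- shape(arc$s[k] + xi * le) * le * 0.5   # Gauss weight 1/2 each
      nodal[k] <- nodal[k] + (1 - xi) * tv
      nodal[k + 1L] <- nodal[k + 1L] + xi * tv
    }
  }
  f <- numeric(2L * nrow(mesh$nodes))
  idx <- 2L * (chain - 1L)
  f[idx + 1L] <- f[idx + 1L] + nodal * thickness * d[1]
  f[idx + 2L] <- f[idx + 2L] + nodal * thickness * d[2]
  f
}

#' Consistent nodal loads of a uniform boundary traction
#'
#' Distributes a total force uniformly along a boundary chain (constant
#' traction magnitude, uniform direction).  Mainly used by the benchmark
#' fixtures, where a uniform end traction produces a uniform uniaxial
#' stress state.
#'
#' @inheritParams parabolic_traction_vector
#' @return Global load vector of length `2 * n_nodes` (N).
#' @export
uniform_traction_vector <- function(mesh, segment, total_force, angle,
                                    sense = "down", thickness = NULL) {
  chain <- resolve_segment(mesh, segment)
  if (length(chain) < 2L) stop("traction needs a segment of at least 2 nodes")
  if (is.null(thickness)) thickness <- mesh$thickness[["FEMUR"]]
  arc <- chain_arclength(mesh, chain)
  if (arc$total <= 0) stop("segment has zero length")
  d <- traction_direction(angle, sense)
  tmag <- total_force / (arc$total * thickness)
  nodal <- numeric(length(chain))
  for (k in seq_len(length(chain) - 1L)) {
    le <- arc$s[k + 1L] - arc$s[k]
    nodal[k] <- nodal[k] + tmag * le / 2
    nodal[k + 1L] <- nodal[k + 1L] + tmag * le / 2
  }
  f <- numeric(2L * nrow(mesh$nodes))
  idx <- 2L * (chain - 1L)
  f[idx + 1L] <- f[idx + 1L] + nodal * thickness * d[1]
  f[idx + 2L] <- f[idx + 2L] + nodal * thickness * d[2]
  f
}

#' Consistent nodal charges of a uniform surface charge density
#'
#' Integrates a uniform surface charge density over a boundary chain
#' (charge per unit area of the lateral slice surface: arc length times
#' thickness).
#'
#' @param mesh A [bone_mesh()].
#' @param segment Boundary segment name or node id chain (>= 2 nodes).
#' @param q_N Surface charge density (C/mm^2), finite.
#' @param thickness Slice thickness (mm); defaults to the femur thickness.
#' @return Global charge vector of length `n_nodes` (C); its sum equals
#'   `q_N * segment length * thickness`.
#' @export
surface_charge_vector <- function(mesh, segment, q_N, thickness = NULL) {
  chain <- resolve_segment(mesh, segment)
  if (length(chain) < 2L) stop("surface charge needs a segment of at least 2 nodes")
  if (!is.finite(q_N)) stop("q_N must be finite")
  if (is.null(thickness)) thickness <- mesh$thickness[["FEMUR"]]
  arc <- chain_arclength(mesh, chain)
  q <- numeric(nrow(mesh$nodes))
  for (k in seq_len(length(chain) - 1L)) {
    le <- arc$s[k + 1L] - arc$s[k]
    half <- q_N * le * thickness / 2
    q[chain[k]] <- q[chain[k]] + half
    q[chain[k + 1L]] <- q[chain[k + 1L]] + half
  }
  q
}

# ---------------------------------------------------------------------------
# Model precomputation.  Geometry-dependent quantities (B, G, areas, base
# stiffness triplets) are computed once; only the per-element density scale
# rho^gamma changes between remodelling steps, because Poisson's ratio is
# density-independent (C(rho) = E(rho) * C_unit) and the coupling and
# permittivity tensors share the alpha(rho) = rho^gamma scale.

build_fem_model <- function(mesh, params, piezo = FALSE) {
  n <- nrow(mesh$nodes)
  ne <- nrow(mesh$elements)
  th <- element_thickness(mesh)
  femur <- mesh$region == "FEMUR"
  Cu_fem <- plane_elastic_unit(params$k, params$lame_convention)
  C_plate <- params$plate_E * plane_elastic_unit(params$plate_k, params$lame_convention)
  e_mat <- rbind(c(0, 0, params$e15),
                 c(params$e31, params$e33, 0))
  beta_mat <- diag(c(params$beta11, params$beta33))
  beta_plate <- diag(c(EPS0_F_PER_MM, EPS0_F_PER_MM))

  areas <- numeric(ne)
  Bs <- vector("list", ne)
  Gs <- vector("list", ne)
  dofm <- matrix(0L, ne, 6)   # global mech dof per local dof
  iuu <- juu <- euu <- integer(0); vuu <- numeric(0); suu <- logical(0)
  iup <- jup <- eup <- integer(0); vup <- numeric(0)
  ipp <- jpp <- epp <- integer(0); vpp <- numeric(0); spp <- logical(0)
  # strain-recovery operator triplets
  ib <- jb <- integer(0); vb <- numeric(0)
  ig <- jg <- integer(0); vg <- numeric(0)

  acc_uu <- vector("list", ne); acc_up <- vector("list", ne)
  acc_pp <- vector("list", ne)
  for (e in seq_len(ne)) {
    en <- mesh$elements[e, ]
    g <- tri_geometry(mesh$nodes[en, , drop = FALSE])
    if (g$area <= 0) stop("element ", e, " has non-positive area")
    areas[e] <- g$area
    Bs[[e]] <- g$B
    Gs[[e]] <- g$G
    dof <- as.integer(rbind(2L * en - 1L, 2L * en))
    dofm[e, ] <- dof
    Cu <- if (femur[e]) Cu_fem else C_plate
    Ke <- g$area * th[e] * crossprod(g$B, Cu %*% g$B)
    acc_uu[[e]] <- list(i = rep(dof, times = 6), j = rep(dof, each = 6),
                        v = as.numeric(Ke))
    if (piezo) {
      if (femur[e]) {
        Ae <- g$area * th[e] * crossprod(g$B, crossprod(e_mat, g$G))  # 6 x 3
        acc_up[[e]] <- list(i = rep(dof, times = 3), j = rep(en, each = 6),
                            v = as.numeric(Ae))
        Pe <- g$area * th[e] * crossprod(g$G, beta_mat %*% g$G)
      } else {
        Pe <- g$area * th[e] * crossprod(g$G, beta_plate %*% g$G)
      }
      acc_pp[[e]] <- list(i = rep(en, times = 3), j = rep(en, each = 3),
                          v = as.numeric(Pe))
    }
    ib <- c(ib, rep(3L * (e - 1L) + 1:3, times = 6))
    jb <- c(jb, rep(dof, each = 3))
    vb <- c(vb, as.numeric(g$B))
    if (piezo) {
      ig <- c(ig, rep(2L * (e - 1L) + 1:2, times = 3))
      jg <- c(jg, rep(en, each = 2))
      vg <- c(vg, as.numeric(g$G))
    }
  }
  iuu <- unlist(lapply(acc_uu, `[[`, "i"))
  juu <- unlist(lapply(acc_uu, `[[`, "j"))
  vuu <- unlist(lapply(acc_uu, `[[`, "v"))
  euu <- rep(seq_len(ne), each = 36L)
  if (piezo) {
    fem_ids <- which(femur)
    iup <- unlist(lapply(acc_up[fem_ids], `[[`, "i"))
    jup <- unlist(lapply(acc_up[fem_ids], `[[`, "j"))
    vup <- unlist(lapply(acc_up[fem_ids], `[[`, "v"))
    eup <- rep(fem_ids, each = 18L)
    ipp <- unlist(lapply(acc_pp, `[[`, "i"))
    jpp <- unlist(lapply(acc_pp, `[[`, "j"))
    vpp <- unlist(lapply(acc_pp, `[[`, "v"))
    epp <- rep(seq_len(ne), each = 9L)
  }

  Bglob <- Matrix::sparseMatrix(i = ib, j = jb, x = vb,
                                dims = c(3L * ne, 2L * n))
  Gglob <- if (piezo)
    Matrix::sparseMatrix(i = ig, j = jg, x = vg, dims = c(2L * ne, n))
  else NULL

  list(mesh = mesh, params = params, piezo = piezo,
       n = n, ne = ne, femur = femur, areas = areas, th = th,
       Cu_fem = Cu_fem, C_plate = C_plate, e_mat = e_mat,
       beta_mat = beta_mat,
       kuu = list(i = iuu, j = juu, v = vuu, e = euu),
       kup = list(i = iup, j = jup, v = vup, e = eup),
       kpp = list(i = ipp, j = jpp, v = vpp, e = epp),
       Bglob = Bglob, Gglob = Gglob)
}

# Per-element stiffness scale for a femur density field (full-length over
# all elements; side-plate elements scale 1).
density_scales <- function(model, rho_femur) {
  p <- model$params
  check_density_bounds(rho_femur, p, "density field")
  if (length(rho_femur) != sum(model$femur))
    stop("density must be defined for every femur element")
  sE <- rep(1, model$ne)
  sA <- rep(1, model$ne)
  rg <- rho_femur^p$gamma
  sE[model$femur] <- p$M * rg       # E(rho) multiplies C_unit
  sA[model$femur] <- rg             # alpha(rho) multiplies e and beta
  list(sE = sE, sA = sA)
}

# Assemble the (full, unconstrained) system matrix for a density field.
model_system_matrix <- function(model, rho_femur) {
  s <- density_scales(model, rho_femur)
  n <- model$n
  ku <- model$kuu
  if (!model$piezo) {
    return(Matrix::sparseMatrix(i = ku$i, j = ku$j, x = ku$v * s$sE[ku$e],
                                dims = c(2L * n, 2L * n)))
  }
  ka <- model$kup
  kp <- model$kpp
  av <- ka$v * s$sA[ka$e]
  Matrix::sparseMatrix(
    i = c(ku$i, ka$i, 2L * n + ka$j, 2L * n + kp$i),
    j = c(ku$j, 2L * n + ka$j, ka$i, 2L * n + kp$j),
    x = c(ku$v * s$sE[ku$e], av, -av, kp$v * s$sA[kp$e]),
    dims = c(3L * n, 3L * n))
}

# Global dof indices (mech interleaved, potential appended) that are fixed
# by the boundary conditions, with their prescribed values.
fixed_dofs <- function(model, bcs, prescribed = NULL) {
  n <- model$n
  idx <- c(2L * bcs$fixed_vertical,                 # y of vertical-fixed
           2L * bcs$fixed_both - 1L, 2L * bcs$fixed_both)
  val <- numeric(length(idx))
  if (model$piezo && length(bcs$grounded)) {
    idx <- c(idx, 2L * n + bcs$grounded)
    val <- c(val, numeric(length(bcs$grounded)))
  }
  if (!is.null(prescribed)) {
    pidx <- ifelse(prescribed$dof == 3L, 2L * n + prescribed$node,
                   2L * (prescribed$node - 1L) + prescribed$dof)
    idx <- c(idx, pidx)
    val <- c(val, prescribed$value)
  }
  keep <- !duplicated(idx)
  list(idx = idx[keep], val = val[keep])
}

# Sparse LU solve with symmetric diagonal equilibration: the coupled
# system mixes stiffness (~1e3 MPa mm) and permittivity (~1e-13 F) scales,
# so the raw matrix is numerically singular for a condition-checked LU.
solve_equilibrated <- function(K, B) {
  d <- sqrt(abs(Matrix::diag(K)))
  d[!is.finite(d) | d == 0] <- 1
  Dinv <- Matrix::Diagonal(x = 1 / d)
  Ks <- Dinv %*% K %*% Dinv
  Y <- Matrix::solve(Ks, B / d)
  as.matrix(Y) / d
}

# Solve K x = F with Dirichlet elimination (exact substitution of the
# prescribed values; row/column reduction, not penalty).
solve_constrained <- function(K, F, fixed) {
  ndof <- nrow(K)
  if (!length(fixed$idx)) stop("no constraints: the system is singular")
  free <- setdiff(seq_len(ndof), fixed$idx)
  F <- as.matrix(F)
  rhs <- F[free, , drop = FALSE]
  if (any(fixed$val != 0))
    rhs <- rhs - as.matrix(K[free, fixed$idx, drop = FALSE] %*% fixed$val)
  Kff <- K[free, free, drop = FALSE]
  x_free <- tryCatch(
    solve_equilibrated(Kff, rhs),
    error = function(e) stop("linear solve failed (insufficient constraints ",
                             "or singular system): ", conditionMessage(e)))
  X <- matrix(0, ndof, ncol(F))
  X[free, ] <- x_free
  X[fixed$idx, ] <- fixed$val
  # relative residual on the constrained equations
  res <- max(apply(as.matrix(Kff %*% x_free) - rhs, 2,
                   function(r) sqrt(sum(r^2))))
  scale <- max(sqrt(colSums(rhs^2)), .Machine$double.eps)
  attr(X, "residual") <- res / scale
  X
}

# Strain, stress and SED recovery for one solution column.
recover_fields <- function(model, rho_femur, u, phi = NULL) {
  s <- density_scales(model, rho_femur)
  eps <- matrix(as.numeric(model$Bglob %*% u), nrow = 3)   # 3 x ne
  stress <- matrix(0, 3, model$ne)
  stress[, model$femur] <- (model$Cu_fem %*% eps[, model$femur, drop = FALSE]) *
    rep(s$sE[model$femur], each = 3)
  if (any(!model$femur))
    stress[, !model$femur] <- model$C_plate %*% eps[, !model$femur, drop = FALSE]
  efield <- NULL
  if (model$piezo && !is.null(phi)) {
    grad <- matrix(as.numeric(model$Gglob %*% phi), nrow = 2)  # 2 x ne
    efield <- -grad
    if (model$params$stimulus == "full_stress") {
      # converse-effect stress -alpha * t(e) E on femur elements
      pz <- crossprod(model$e_mat, efield[, model$femur, drop = FALSE])
      stress[, model$femur] <- stress[, model$femur] -
        pz * rep(s$sA[model$femur], each = 3)
    }
  }
  sed <- 0.5 * colSums(stress * eps)
  list(strain = eps, stress = stress, sed = sed, efield = efield)
}

#' Assemble the global system blocks
#'
#' Builds the sparse global blocks of the (optionally coupled) quasi-static
#' problem for a given femur density field: the mechanical stiffness
#' `K_uu`, and for the coupled model the coupling blocks `K_uphi` (entering
#' the displacement equation) and `K_phiu` (entering the potential
#' equation, assembled independently from the electric weak form) and the
#' dielectric block `K_phiphi`.
#'
#' @param mesh A [bone_mesh()].
#' @param density Apparent density per femur element (g/cm^3).
#' @param params A [material_params()].
#' @param piezo Assemble the coupled blocks?
#' @return List with `K_uu` (2n x 2n) and, if `piezo`, `K_uphi` (2n x n),
#'   `K_phiu` (n x 2n), `K_phiphi` (n x n), all `dgCMatrix`.
#' @export
assemble_system <- function(mesh, density, params = material_params(),
                            piezo = FALSE) {
  model <- build_fem_model(mesh, params, piezo)
  s <- density_scales(model, density)
  n <- model$n
  ku <- model$kuu
  out <- list(K_uu = Matrix::sparseMatrix(
    i = ku$i, j = ku$j, x = ku$v * s$sE[ku$e], dims = c(2L * n, 2L * n)))
  if (piezo) {
    ka <- model$kup
    kp <- model$kpp
    out$K_uphi <- Matrix::sparseMatrix(i = ka$i, j = ka$j,
                                       x = ka$v * s$sA[ka$e],
                                       dims = c(2L * n, n))
    # electric-route assembly of the transposed coupling (independent loop)
    fem_ids <- which(model$femur)
    ii <- jj <- integer(0); vv <- numeric(0)
    acc <- vector("list", length(fem_ids))
    for (k in seq_along(fem_ids)) {
      e <- fem_ids[k]
      en <- mesh$elements[e, ]
      g <- tri_geometry(mesh$nodes[en, , drop = FALSE])
      Ce <- model$areas[e] * model$th[e] * s$sA[e] *
        crossprod(g$G, model$e_mat %*% g$B)          # 3 x 6
      dof <- as.integer(rbind(2L * en - 1L, 2L * en))
      acc[[k]] <- list(i = rep(en, times = 6), j = rep(dof, each = 3),
                       v = as.numeric(Ce))
    }
    out$K_phiu <- Matrix::sparseMatrix(
      i = unlist(lapply(acc, `[[`, "i")),
      j = unlist(lapply(acc, `[[`, "j")),
      x = unlist(lapply(acc, `[[`, "v")), dims = c(n, 2L * n))
    out$K_phiphi <- Matrix::sparseMatrix(i = kp$i, j = kp$j,
                                         x = kp$v * s$sA[kp$e],
                                         dims = c(n, n))
  }
  out
}

# Build the mechanical (and electrical) load vectors for one load set.
build_loads <- function(model, loads) {
  n <- model$n
  f <- numeric(2L * n)
  q <- numeric(n)
  mesh <- model$mesh
  if (!is.null(loads$tractions)) for (tr in loads$tractions) {
    f <- f + parabolic_traction_vector(mesh, tr$segment, tr$force, tr$angle,
                                       sense = tr$sense %||% "down",
                                       thickness = tr$thickness)
  }
  if (!is.null(loads$f_ext)) f <- f + loads$f_ext
  if (!is.null(loads$charge) && !is.null(loads$charge$segment) &&
      loads$charge$q != 0) {
    q <- q + surface_charge_vector(mesh, loads$charge$segment, loads$charge$q,
                                   thickness = loads$charge$thickness)
  }
  if (!is.null(loads$q_ext)) q <- q + loads$q_ext
  if (model$piezo) c(f, q) else f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve one quasi-static (coupled) elasticity problem
#'
#' Assembles the system for the given density field, applies the boundary
#' conditions by exact row/column elimination, solves by sparse LU, and
#' recovers per-element strain, stress, strain energy density and (coupled
#' model) electric field.
#'
#' @param mesh A [bone_mesh()].
#' @param density Apparent density per femur element (g/cm^3).
#' @param params A [material_params()].
#' @param bcs A [boundary_conditions()] object.
#' @param loads List describing the load set:
#'   `tractions` (list of `list(segment, force, angle, sense)`), `charge`
#'   (`list(segment, q)`), and/or raw vectors `f_ext` (length 2n), `q_ext`
#'   (length n).
#' @param piezo Solve the coupled piezoelectric problem?
#' @param prescribed Optional data frame `node`, `dof` (1 = x, 2 = y,
#'   3 = potential), `value` of additional Dirichlet constraints (used e.g.
#'   by patch tests).
#' @return Object of class `fem_solution`: `u` (n x 2, mm), `phi` (V or
#'   `NULL`), `strain` (3 x ne), `stress` (3 x ne, MPa), `sed` (MPa),
#'   `efield` (2 x ne, V/mm or `NULL`), `residual` (relative).
#' @export
solve_quasistatic <- function(mesh, density, params = material_params(),
                              bcs = boundary_conditions(mesh),
                              loads = list(), piezo = FALSE,
                              prescribed = NULL) {
  model <- build_fem_model(mesh, params, piezo)
  K <- model_system_matrix(model, density)
  F <- build_loads(model, loads)
  fixed <- fixed_dofs(model, bcs, prescribed)
  X <- solve_constrained(K, F, fixed)
  n <- model$n
  u <- X[seq_len(2L * n), 1]
  phi <- if (piezo) X[2L * n + seq_len(n), 1] else NULL
  fields <- recover_fields(model, density, u, phi)
  structure(list(u = matrix(u, ncol = 2, byrow = TRUE),
                 phi = phi,
                 strain = fields$strain, stress = fields$stress,
                 sed = fields$sed, efield = fields$efield,
                 residual = attr(X, "residual"),
                 f_ext = if (piezo) F[seq_len(2L * n)] else F),
            class = "fem_solution")
}

#' @export
print.fem_solution <- function(x, ...) {
  cat("<fem_solution> ", nrow(x$u), " nodes",
      if (!is.null(x$phi)) ", coupled (potential solved)", "\n", sep = "")
  cat(sprintf("  max |u| = %.4g mm; max SED = %.4g MPa; residual = %.2g\n",
              max(abs(x$u)), max(x$sed), x$residual))
  if (!is.null(x$phi))
    cat(sprintf("  potential range [%.4g, %.4g] V\n",
                min(x$phi), max(x$phi)))
  invisible(x)
}

#' Strain energy density of a solved state
#'
#' \eqn{U = \frac{1}{2}\sigma : \epsilon} per element, evaluated at the
#' (constant) element strain with the full constitutive stress in force.
#'
#' @param state A [solve_quasistatic()] solution.
#' @param element Optional element index/indices.
#' @return SED in MPa (1 MPa = 1 J/cm^3).
#' @export
strain_energy_density <- function(state, element = NULL) {
  stopifnot(inherits(state, "fem_solution"))
  if (is.null(element)) state$sed else state$sed[element]
}
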