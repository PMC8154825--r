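# Shared fixtures and independent oracles for the test suite.
# Everything is built in code; no stored binary data.

table1 <- material_params()

# --- minimal MSH v2 fixtures -----------------------------------------------

# unit square split into two triangles, one FEMUR region, bottom edge tagged
write_two_triangle_msh <- function(path = tempfile(fileext = ".msh"),
                                   with_names = TRUE) {
  lines <- c(
    "$MeshFormat", "2.2 0 8", "$EndMeshFormat",
    if (with_names) c("$PhysicalNames", "2",
                      '2 1 "FEMUR"', '1 2 "BOTTOM_EDGE"',
                      "$EndPhysicalNames"),
    "$Nodes", "4",
    "1 0 0 0", "2 1 0 0", "3 1 1 0", "4 0 1 0",
    "$EndNodes",
    "$Elements", "3",
    "1 1 2 2 2 1 2",
    "2 2 2 1 1 1 2 3",
    "3 2 2 1 1 1 3 4",
    "$EndElements")
  writeLines(lines, path)
  path
}

# one-triangle prism extruded in z and split into three tetrahedra: a
# minimal one-element-thick slice mesh for the flattening path
write_prism_tet_msh <- function(path = tempfile(fileext = ".msh")) {
  lines <- c(
    "$MeshFormat", "2.2 0 8", "$EndMeshFormat",
    "$PhysicalNames", "1", '3 1 "FEMUR"', "$EndPhysicalNames",
    "$Nodes", "6",
    "1 0 0 0", "2 1 0 0", "3 0 1 0",
    "4 0 0 1", "5 1 0 1", "6 0 1 1",
    "$EndNodes",
    "$Elements", "3",
    "1 4 2 1 1 1 2 3 4",
    "2 4 2 1 1 2 3 4 5",
    "3 4 2 1 1 3 4 5 6",
    "$EndElements")
  writeLines(lines, path)
  path
}

# --- independent mechanical oracles ----------------------------------------

# Strain of the linear interpolant of nodal displacements on a triangle,
# computed from a plane fit (independent of the package's B-matrix).
fit_strain <- function(coords, u6) {
  A <- cbind(1, coords[, 1], coords[, 2])
  cx <- solve(A, u6[c(1, 3, 5)])   # ux = a + b x + c y
  cy <- solve(A, u6[c(2, 4, 6)])
  c(cx[2], cy[3], cx[3] + cy[2])   # (exx, eyy, gxy)
}

# Dense element stiffness via the energy bilinear form with plane-fit
# strains (constant over the triangle, so one evaluation is exact).
oracle_element_stiffness <- function(coords, C, thickness) {
  area <- 0.5 * abs(det(cbind(coords[2, ] - coords[1, ],
                              coords[3, ] - coords[1, ])))
  K <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    ei <- numeric(6); ei[i] <- 1
    ej <- numeric(6); ej[j] <- 1
    K[i, j] <- area * thickness *
      sum(fit_strain(coords, ei) * (C %*% fit_strain(coords, ej)))
  }
  K
}

# Dense global assembly oracle (femur-only meshes).
oracle_assemble_dense <- function(mesh, density, params) {
  n <- nrow(mesh$nodes)
  K <- matrix(0, 2 * n, 2 * n)
  for (e in seq_len(nrow(mesh$elements))) {
    en <- mesh$elements[e, ]
    C <- plane_tensors(density[e], params, "FEMUR")$C
    Ke <- oracle_element_stiffness(mesh$nodes[en, , drop = FALSE], C,
                                   mesh$thickness[["FEMUR"]])
    dof <- as.integer(rbind(2 * en - 1, 2 * en))
    K[dof, dof] <- K[dof, dof] + Ke
  }
  K
}

# Forward integration of the single-element remodelling ODE at tiny dt:
# independent of the package's stepping code.
oracle_bar_ode <- function(rho0, sigma, t_end, params = table1,
                           dt = 0.005) {
  rho <- rho0
  for (i in seq_len(round(t_end / dt))) {
    U <- sigma^2 / (2 * params$M * rho^params$gamma)
    rho <- rho + dt * params$B * (U / rho - params$S_r)
    rho <- min(max(rho, params$rho_min), params$rho_max)
  }
  rho
}

# --- common boundary-condition helpers -------------------------------------

bar_axial_setup <- function(mesh, sigma, width = 10, thickness = 1) {
  list(
    bcs = boundary_conditions(mesh, fixed_vertical = "BOTTOM_EDGE",
                              fixed_both = mesh$boundaries$BOTTOM_EDGE[1],
                              grounded = NULL),
    f = uniform_traction_vector(mesh, "TOP_EDGE", sigma * width * thickness,
                                0, "up")
  )
}

resultant_of <- function(f) {
  fx <- sum(f[seq(1, length(f), 2)])
  fy <- sum(f[seq(2, length(f), 2)])
  c(fx = fx, fy = fy, mag = sqrt(fx^2 + fy^2))
}
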