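test_that("element stiffness matches the independent energy oracle", {
  set.seed(11)
  for (i in 1:4) {
    coords <- matrix(runif(6, 0, 10), 3, 2)
    if (det(cbind(coords[2, ] - coords[1, ], coords[3, ] - coords[1, ])) < 0)
      coords <- coords[c(1, 3, 2), ]
    A <- matrix(rnorm(9), 3, 3)
    C <- crossprod(A) + diag(3)          # random SPD
    th <- runif(1, 0.1, 2)
    K <- element_stiffness(coords, C, th)
    expect_equal(K, oracle_element_stiffness(coords, C, th),
                 tolerance = 1e-12)
    expect_equal(K, t(K), tolerance = 1e-12)
    # rigid modes in the kernel: two translations and the linearised rotation
    tx <- rep(c(1, 0), 3); ty <- rep(c(0, 1), 3)
    rot <- as.numeric(t(cbind(-coords[, 2], coords[, 1])))
    for (v in list(tx, ty, rot))
      expect_lt(max(abs(K %*% v)), 1e-10 * max(abs(K)))
    # thickness is a linear multiplier
    expect_equal(element_stiffness(coords, C, 2 * th), 2 * K,
                 tolerance = 1e-12)
  }
  expect_error(element_stiffness(matrix(c(0, 0, 1, 1, 2, 2), 3, 2,
                                        byrow = TRUE), diag(3)),
               "degenerate")
})

test_that("parabolic tractions reproduce the gait-load resultants", {
  m <- generate_femur2d(femur2d_spec(resolution = 0.6))
  lc <- default_load_cases()
  for (r in seq_len(nrow(lc))) {
    fh <- parabolic_traction_vector(m, "HEAD_ARC", lc$head_force[r],
                                    lc$head_angle[r], "down")
    rh <- resultant_of(fh)
    expect_equal(unname(rh["mag"]), lc$head_force[r], tolerance = 1e-8)
    a <- lc$head_angle[r] * pi / 180
    expect_equal(unname(rh[c("fx", "fy")]),
                 lc$head_force[r] * c(sin(a), -cos(a)), tolerance = 1e-8)
    ft <- parabolic_traction_vector(m, "TROCHANTER_ARC", lc$troch_force[r],
                                    lc$troch_angle[r], "up")
    rt <- resultant_of(ft)
    expect_equal(unname(rt["mag"]), lc$troch_force[r], tolerance = 1e-8)
    # abductor reaction opposes the joint load vertically
    expect_true(rt["fy"] > 0 && rh["fy"] < 0)
  }
  # parabola symmetry: midpoint node carries the maximum nodal load
  mb <- generate_bar_mesh(100, 10, 8, 4)
  f <- parabolic_traction_vector(mb, "LEFT_EDGE", 100, 0, "down")
  chain <- mb$boundaries$LEFT_EDGE
  mags <- abs(f[2 * chain])
  expect_equal(which.max(mags), (length(chain) + 1) %/% 2)
  # the traction profile vanishes at the chain ends, so the consistent end
  # nodal loads are far below the midpoint load
  expect_lt(mags[1], max(mags) / 4)
  expect_lt(mags[length(mags)], max(mags) / 4)
  expect_error(parabolic_traction_vector(mb, mb$boundaries$LEFT_EDGE[1:2],
                                         10, 0), "at least 3 nodes")
})

test_that("surface charge integrates q_N over the segment area", {
  m <- generate_bar_mesh(100, 10, 10, 2)
  q <- surface_charge_vector(m, "LEFT_EDGE", 2e-9, thickness = 1)
  expect_equal(sum(q), 2e-9 * 100 * 1, tolerance = 1e-10)
  expect_true(all(surface_charge_vector(m, "LEFT_EDGE", 0) == 0))
  # halving segment length halves the total
  half <- m$boundaries$LEFT_EDGE[1:6]   # 50 mm of the 100 mm edge
  expect_equal(sum(surface_charge_vector(m, half, 2e-9)), 1e-7)
  expect_error(surface_charge_vector(m, integer(), 1e-9), "at least 2")
})

test_that("global assembly matches a dense oracle and the density scaling law", {
  p <- table1
  m <- read_gmsh_mesh(write_two_triangle_msh(), thickness = c(FEMUR = 1))
  dens <- c(0.6, 1.1)
  blocks <- assemble_system(m, dens, p)
  expect_null(blocks$K_uphi)
  expect_equal(as.matrix(blocks$K_uu), oracle_assemble_dense(m, dens, p),
               tolerance = 1e-10, ignore_attr = TRUE)
  # uniform rho = 0.8 scales the unit-density stiffness by 0.8^3
  mb <- generate_bar_mesh(20, 10, 2, 2)
  K1 <- assemble_system(mb, rep(1, 8), p)$K_uu
  K08 <- assemble_system(mb, rep(0.8, 8), p)$K_uu
  expect_equal(as.matrix(K08), 0.8^3 * as.matrix(K1), tolerance = 1e-12)
  expect_error(assemble_system(mb, rep(0.8, 5), p), "every femur element")
})

test_that("coupled blocks have the transpose structure and K_phiphi is SPD", {
  p <- table1
  mb <- generate_bar_mesh(20, 10, 3, 2)
  rho <- seq(0.3, 1.2, length.out = sum(mb$region == "FEMUR"))
  bl <- assemble_system(mb, rho, p, piezo = TRUE)
  expect_lt(max(abs(bl$K_phiu - Matrix::t(bl$K_uphi))),
            1e-14 * max(abs(bl$K_uphi)))
  expect_lt(max(abs(bl$K_uu - Matrix::t(bl$K_uu))), 1e-12 * max(abs(bl$K_uu)))
  # grounded dielectric block is SPD
  grounded <- mb$boundaries$BOTTOM_EDGE
  free <- setdiff(seq_len(nrow(mb$nodes)), grounded)
  Kpp <- as.matrix(bl$K_phiphi[free, free])
  expect_true(all(eigen(Kpp, symmetric = TRUE)$values > 0))
})

test_that("linear displacement fields are reproduced exactly (patch tests)", {
  p <- table1
  A <- matrix(c(2e-4, 1e-4, -3e-5, 5e-5), 2, 2)
  expected <- c(A[1, 1], A[2, 2], A[1, 2] + A[2, 1])
  run_patch <- function(m, rho) {
    bnd <- sort(unique(unlist(m$boundaries)))
    ub <- m$nodes[bnd, ] %*% t(A)
    presc <- rbind(data.frame(node = bnd, dof = 1, value = ub[, 1]),
                   data.frame(node = bnd, dof = 2, value = ub[, 2]))
    sol <- solve_quasistatic(m, rho, p,
                             boundary_conditions(m, NULL, NULL, grounded = NULL),
                             prescribed = presc)
    max(abs(sol$strain - expected))
  }
  # interior nodes, uniform density
  m1 <- generate_bar_mesh(30, 20, 5, 3)
  expect_lt(run_patch(m1, rep(0.9, sum(m1$region == "FEMUR"))), 1e-10)
  # heterogeneous density: every node prescribed (one-element-thick strip)
  set.seed(3)
  m2 <- generate_bar_mesh(30, 20, 6, 1)
  expect_lt(run_patch(m2, runif(sum(m2$region == "FEMUR"), 0.2, 1.5)), 1e-10)
})

test_that("cantilever tip deflection converges to a fine-mesh reference", {
  p <- table1
  tip <- function(nx, ny) {
    m <- generate_bar_mesh(40, 10, nx, ny)
    bcs <- boundary_conditions(m, NULL, "BOTTOM_EDGE", grounded = NULL)
    f <- uniform_traction_vector(m, "TOP_EDGE", 10, 90, "down")
    sol <- solve_quasistatic(m, rep(0.8, sum(m$region == "FEMUR")), p, bcs,
                             loads = list(f_ext = f))
    mean(sol$u[m$boundaries$TOP_EDGE, 1])
  }
  coarse <- tip(48, 12)
  fine <- tip(96, 24)
  expect_lt(abs(coarse - fine) / abs(fine), 0.02)
})

test_that("piezo bar reproduces the open-circuit closed form", {
  p <- table1
  m <- generate_bar_mesh(100, 10, 8, 2)
  n <- nrow(m$nodes)
  eps <- 1e-3
  presc <- rbind(data.frame(node = 1:n, dof = 1, value = 0),
                 data.frame(node = 1:n, dof = 2, value = eps * m$nodes[, 2]))
  bcs <- boundary_conditions(m, NULL, NULL, grounded = "BOTTOM_EDGE")
  sol <- solve_quasistatic(m, rep(1, sum(m$region == "FEMUR")), p, bcs,
                           piezo = TRUE, prescribed = presc)
  phi_tip <- mean(sol$phi[m$boundaries$TOP_EDGE])
  expected <- analytic_piezo_bar_potential(eps * elastic_modulus(1, p), 100, 1, p)
  expect_equal(phi_tip, expected, tolerance = 1e-6)
  expect_equal(abs(phi_tip), 1.7621, tolerance = 1e-4)
  # sigma = 0: no strain, no potential
  sol0 <- solve_quasistatic(m, rep(1, sum(m$region == "FEMUR")), p,
                            boundary_conditions(m, "BOTTOM_EDGE",
                                                m$boundaries$BOTTOM_EDGE[1],
                                                grounded = "BOTTOM_EDGE"),
                            piezo = TRUE)
  expect_lt(max(abs(sol0$phi)), 1e-12)
})

test_that("strain energy density matches closed forms and Clapeyron's theorem", {
  # uniaxial sigma = 1 MPa at E = 1000 MPa, k = 0: U = sigma^2/(2E) = 5e-4
  p <- material_params(M = 1000, gamma = 3, k = 0)
  m <- generate_bar_mesh(50, 10, 5, 2)
  st <- bar_axial_setup(m, 1)
  sol <- solve_quasistatic(m, rep(1, sum(m$region == "FEMUR")), p, st$bcs,
                           loads = list(f_ext = st$f))
  expect_equal(unname(range(sol$sed)), c(5e-4, 5e-4), tolerance = 1e-10)
  expect_true(all(strain_energy_density(sol) >= 0))
  # Clapeyron: total strain energy equals half the external work
  p2 <- table1
  mf <- generate_femur2d(femur2d_spec(resolution = 0.6))
  rho <- rep(0.8, sum(mf$region == "FEMUR"))
  lc <- default_load_cases()[1, ]
  sol2 <- solve_quasistatic(mf, rho, p2, boundary_conditions(mf),
                            loads = list(tractions = list(
                              list(segment = "HEAD_ARC", force = lc$head_force,
                                   angle = lc$head_angle, sense = "down"),
                              list(segment = "TROCHANTER_ARC",
                                   force = lc$troch_force,
                                   angle = lc$troch_angle, sense = "up"))))
  w <- abs(element_areas(mf)) * piezobone:::element_thickness(mf)
  total_U <- sum(sol2$sed * w)
  work <- 0.5 * sum(sol2$f_ext * as.numeric(t(sol2$u)))
  expect_equal(total_U, work, tolerance = 1e-8)
})

test_that("discrete Betti reciprocity links traction and charge responses", {
  p <- table1
  mb <- generate_bar_mesh(20, 10, 3, 2)
  rho <- seq(0.3, 1.2, length.out = sum(mb$region == "FEMUR"))
  bcs <- boundary_conditions(mb, "BOTTOM_EDGE", mb$boundaries$BOTTOM_EDGE[1],
                             grounded = "BOTTOM_EDGE")
  f <- uniform_traction_vector(mb, "TOP_EDGE", 5, 10, "up")
  qv <- surface_charge_vector(mb, "RIGHT_EDGE", 3e-9)
  s_f <- solve_quasistatic(mb, rho, p, bcs, loads = list(f_ext = f),
                           piezo = TRUE)
  s_q <- solve_quasistatic(mb, rho, p, bcs, loads = list(q_ext = qv),
                           piezo = TRUE)
  lhs <- sum(f * as.numeric(t(s_q$u)))
  rhs <- -sum(qv * s_f$phi)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("the solution is invariant under node renumbering", {
  p <- table1
  m <- generate_bar_mesh(40, 10, 4, 2)
  nf <- sum(m$region == "FEMUR")
  set.seed(5)
  rho <- runif(nf, 0.3, 1.5)
  st <- bar_axial_setup(m, 2)
  sol <- solve_quasistatic(m, rho, p, st$bcs, loads = list(f_ext = st$f))
  # permute the nodes and remap everything
  perm <- sample(nrow(m$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  m2 <- bone_mesh(m$nodes[perm, ], matrix(inv[m$elements], ncol = 3),
                  m$region, lapply(m$boundaries, function(ch) inv[ch]),
                  m$thickness)
  st2 <- bar_axial_setup(m2, 2)
  sol2 <- solve_quasistatic(m2, rho, p, st2$bcs, loads = list(f_ext = st2$f))
  expect_equal(sol2$u[inv, ], sol$u, tolerance = 1e-10)
  expect_equal(sol2$sed, sol$sed, tolerance = 1e-10)
})

test_that("underconstrained systems fail with a solver diagnostic", {
  m <- generate_bar_mesh(20, 10, 2, 2)
  rho <- rep(0.8, sum(m$region == "FEMUR"))
  bcs <- boundary_conditions(m, NULL, NULL, grounded = NULL)
  expect_error(solve_quasistatic(m, rho, table1, bcs), "constraint|singular")
})
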