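# Programmatic benchmark geometries and analytic oracles.
#
# Everything here is deterministic: regenerating a fixture from the same
# spec gives a bit-identical mesh.

#' Structured rectangular bar mesh
#'
#' A vertical bar (axial direction along the global y axis, which is the
#' poling direction of the plane model) triangulated on a structured grid.
#' Boundary chains: `BOTTOM_EDGE`, `TOP_EDGE`, `LEFT_EDGE`, `RIGHT_EDGE`.
#'
#' @param length Axial length (mm), along y.
#' @param width Width (mm), along x.
#' @param nx Number of element divisions along the length.
#' @param ny Number of element divisions across the width.
#' @param thickness Out-of-plane thickness (mm).
#' @return A [bone_mesh()] with a single `FEMUR` region,
#'   `2 * nx * ny` triangles and `(nx + 1) * (ny + 1)` nodes.
#' @examples
#' m <- generate_bar_mesh(100, 10, 10, 2)
#' nrow(m$elements)  # 40
#' @export
generate_bar_mesh <- function(length = 100, width = 10, nx = 10, ny = 2,
                              thickness = 1) {
  stopifnot(length > 0, width > 0, nx >= 1, ny >= 1)
  xs <- seq(0, width, length.out = ny + 1)
  ys <- seq(0, length, length.out = nx + 1)
  nodes <- cbind(rep(xs, times = nx + 1), rep(ys, each = ny + 1))
  gid <- function(i, j) j * (ny + 1L) + i + 1L   # i across width, j along length
  quads <- expand.grid(i = 0:(ny - 1L), j = 0:(nx - 1L))
  n00 <- gid(quads$i, quads$j)
  n10 <- gid(quads$i + 1L, quads$j)
  n11 <- gid(quads$i + 1L, quads$j + 1L)
  n01 <- gid(quads$i, quads$j + 1L)
  elements <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))
  boundaries <- list(
    BOTTOM_EDGE = gid(0:ny, 0L),
    TOP_EDGE = gid(0:ny, nx),
    LEFT_EDGE = gid(0L, 0:nx),
    RIGHT_EDGE = gid(ny, 0:nx)
  )
  bone_mesh(nodes, elements, rep("FEMUR", nrow(elements)),
            boundaries = boundaries, thickness = c(FEMUR = thickness))
}

#' Specification for the stylised 2-D proximal femur fixture
#'
#' Parameters of the parametric femur-like contour: a shaft with an
#' intramedullary gap closed by a side-plate, a metaphyseal flare, a
#' greater-trochanter bump on the lateral boundary, and a circular femoral
#' head capped by the head arc.  The published landmark distances are
#' generator constraints: the P-Q distance (top of the side-plate trapezoid)
#' and the R-S distance (diaphysis diameter) are met exactly by
#' construction.
#'
#' @param resolution Scale factor on the default grid (`nx = 14 * resolution`
#'   columns, `ny = 57 * resolution` rows); element count grows roughly with
#'   `resolution^2`.
#' @param nx,ny Explicit grid overrides.
#' @param pq_distance Distance between landmarks P and Q (mm).
#' @param rs_distance Diaphysis diameter, landmarks R to S (mm).
#' @param shaft_height Height of the side-plate trapezoid (mm).
#' @param cortical_fraction Fraction of grid columns forming each cortical
#'   wall of the shaft; the columns between them are the medullary gap.
#' @param gap_top_fraction Fraction of the shaft height over which the
#'   medullary gap extends.
#' @param head_center,head_radius Femoral head circle (mm).
#' @param head_arc_deg Angular span of the top boundary on the head circle.
#' @param load_arc_deg Angular span of the `HEAD_ARC` load segment
#'   (centred on the top of the head).
#' @param trochanter_span Fractions (of the left boundary parameter) between
#'   which the `TROCHANTER_ARC` chain runs.
#' @param femur_thickness,plate_thickness Out-of-plane thickness (mm).
#' @return A list of class `femur2d_spec`.
#' @export
femur2d_spec <- function(resolution = 1, nx = NULL, ny = NULL,
                         pq_distance = 66.59, rs_distance = 34.10,
                         shaft_height = 40,
                         cortical_fraction = 0.25, gap_top_fraction = 0.8,
                         head_center = c(44, 96), head_radius = 25,
                         head_arc_deg = 120, load_arc_deg = 60,
                         trochanter_span = c(0.46, 0.64),
                         femur_thickness = 1, plate_thickness = 0.1) {
  if (is.null(nx)) nx <- max(4L, as.integer(round(14 * resolution)))
  if (is.null(ny)) ny <- max(9L, as.integer(round(57 * resolution)))
  spec <- list(nx = nx, ny = ny, pq_distance = pq_distance,
               rs_distance = rs_distance, shaft_height = shaft_height,
               cortical_fraction = cortical_fraction,
               gap_top_fraction = gap_top_fraction,
               head_center = head_center, head_radius = head_radius,
               head_arc_deg = head_arc_deg, load_arc_deg = load_arc_deg,
               trochanter_span = trochanter_span,
               femur_thickness = femur_thickness,
               plate_thickness = plate_thickness)
  if (pq_distance <= rs_distance)
    stop("infeasible femur spec: pq_distance must exceed rs_distance")
  if (shaft_height <= 0 || head_radius <= 0)
    stop("infeasible femur spec: non-positive dimensions")
  structure(spec, class = "femur2d_spec")
}

# Split structured quads into triangles, choosing per quad the diagonal
# that maximises the minimum signed triangle area (keeps skewed
# boundary-fitted cells valid).
split_quads_adaptive <- function(nodes, n00, n10, n11, n01) {
  tri_area <- function(a, b, c)
    0.5 * ((nodes[b, 1] - nodes[a, 1]) * (nodes[c, 2] - nodes[a, 2]) -
             (nodes[c, 1] - nodes[a, 1]) * (nodes[b, 2] - nodes[a, 2]))
  a1 <- pmin(tri_area(n00, n10, n11), tri_area(n00, n11, n01))
  a2 <- pmin(tri_area(n10, n11, n01), tri_area(n10, n01, n00))
  use1 <- a1 >= a2
  rbind(cbind(ifelse(use1, n00, n10), ifelse(use1, n10, n11),
              ifelse(use1, n11, n01)),
        cbind(ifelse(use1, n00, n10), ifelse(use1, n11, n01),
              ifelse(use1, n01, n00)))
}

# Height-parametrised contour through control points (x single-valued in
# y, which keeps the structured grid rows monotone in height): maps the
# parameter range [t0, 1] linearly onto the height range of the controls.
curve_through <- function(pts, t0, t1) {
  y0 <- pts[1, 2]; y1 <- pts[nrow(pts), 2]
  if (any(diff(pts[, 2]) <= 0))
    stop("contour control points must increase strictly in height")
  fx <- stats::splinefun(pts[, 2], pts[, 1], method = "natural")
  function(t) {
    y <- y0 + (t - t0) / (t1 - t0) * (y1 - y0)
    cbind(fx(y), y)
  }
}

#' Generate the stylised 2-D proximal femur mesh
#'
#' Builds a boundary-fitted structured grid (a Coons patch between the flat
#' resection plane at the bottom, the femoral head arc at the top, and
#' lateral/medial contour splines) and triangulates it.  The medullary-gap
#' elements of the shaft are removed and a `SIDE_PLATE` region spanning the
#' whole shaft trapezoid is added with its own interior nodes, joined to the
#' femur only along the `SHARED_LATERAL` (P-R) and `SHARED_MEDIAL` (Q-S)
#' chains.  Landmarks P, Q, R, S, T are stored on the mesh; `|PQ|` and
#' `|RS|` equal the spec distances exactly.
#'
#' @param spec A [femur2d_spec()].
#' @return A [bone_mesh()] with boundary chains `HEAD_ARC`,
#'   `TROCHANTER_ARC`, `BOTTOM_EDGE`, `LEFT_EDGE`, `SHARED_LATERAL`,
#'   `SHARED_MEDIAL`.
#' @export
generate_femur2d <- function(spec = femur2d_spec()) {
  stopifnot(inherits(spec, "femur2d_spec"))
  nx <- spec$nx; ny <- spec$ny
  cx <- spec$rs_distance / 2
  R0 <- c(0, 0)
  S0 <- c(spec$rs_distance, 0)
  P <- c(cx - spec$pq_distance / 2, spec$shaft_height)
  Q <- c(cx + spec$pq_distance / 2, spec$shaft_height)
  Ch <- spec$head_center; rh <- spec$head_radius
  half <- spec$head_arc_deg / 2
  th0 <- (90 + half) * pi / 180
  th1 <- (90 - half) * pi / 180
  A0 <- Ch + rh * c(cos(th0), sin(th0))
  A1 <- Ch + rh * c(cos(th1), sin(th1))

  t_shaft <- 1 / 3
  j_s <- as.integer(round(ny * t_shaft))
  t_shaft <- j_s / ny   # snap so grid row j_s lands exactly on P and Q

  # lateral (left) contour: straight shaft edge R-P, then trochanter bump
  # and saddle up to the head-arc start
  hs <- spec$shaft_height
  Lctrl <- rbind(P,
                 c(P[1] - 7, hs + 14),
                 c(P[1] - 8, hs + 24),   # greater-trochanter bump apex
                 c(P[1] + 2, hs + 34),
                 c(6, hs + 44),          # trochanteric saddle
                 c(A0[1] - 6, A0[2] - 14),
                 c(A0[1] - 2, A0[2] - 7),
                 A0)
  Lspline <- curve_through(Lctrl, t_shaft, 1)
  Lfun <- function(t) {
    t <- pmin(pmax(t, 0), 1)
    lower <- t <= t_shaft
    out <- matrix(0, length(t), 2)
    if (any(lower)) {
      u <- t[lower] / t_shaft
      out[lower, ] <- cbind(R0[1] + u * (P[1] - R0[1]),
                            R0[2] + u * (P[2] - R0[2]))
    }
    if (any(!lower)) out[!lower, ] <- Lspline(t[!lower])
    out
  }
  # medial (right) contour: straight shaft edge S-Q, then calcar curve up to
  # the head-arc end
  Rctrl <- rbind(Q,
                 c(Q[1] + 6, hs + 18),
                 c(Q[1] + 12, hs + 32),
                 c((Q[1] + 12 + A1[1]) / 2 + 4, (hs + 32 + A1[2]) / 2),
                 A1)
  Rspline <- curve_through(Rctrl, t_shaft, 1)
  Rfun <- function(t) {
    t <- pmin(pmax(t, 0), 1)
    lower <- t <= t_shaft
    out <- matrix(0, length(t), 2)
    if (any(lower)) {
      u <- t[lower] / t_shaft
      out[lower, ] <- cbind(S0[1] + u * (Q[1] - S0[1]),
                            S0[2] + u * (Q[2] - S0[2]))
    }
    if (any(!lower)) out[!lower, ] <- Rspline(t[!lower])
    out
  }
  Bfun <- function(s) cbind(R0[1] + s * (S0[1] - R0[1]), 0 * s)
  Tfun <- function(s) {
    th <- th0 + s * (th1 - th0)
    cbind(Ch[1] + rh * cos(th), Ch[2] + rh * sin(th))
  }

  # Coons patch over the unit square
  s <- rep(seq(0, 1, length.out = nx + 1), times = ny + 1)
  t <- rep(seq(0, 1, length.out = ny + 1), each = nx + 1)
  Bv <- Bfun(s); Tv <- Tfun(s); Lv <- Lfun(t); Rv <- Rfun(t)
  blend <- function(col)
    (1 - t) * Bv[, col] + t * Tv[, col] + (1 - s) * Lv[, col] + s * Rv[, col] -
      ((1 - s) * (1 - t) * R0[col] + s * (1 - t) * S0[col] +
         (1 - s) * t * A0[col] + s * t * A1[col])
  nodes <- cbind(blend(1), blend(2))
  gid <- function(i, j) j * (nx + 1L) + i + 1L

  # the shaft block is the straight trapezoid R-S-Q-P: rows up to j_s
  # interpolate linearly between the resection plane and the P-Q chord
  for (j in 0:j_s) {
    u <- j / j_s
    sv <- seq(0, 1, length.out = nx + 1)
    lower <- Bfun(sv)
    upper <- cbind(P[1] + sv * (Q[1] - P[1]), P[2] + sv * (Q[2] - P[2]))
    nodes[gid(0:nx, j), ] <- (1 - u) * lower + u * upper
  }

  # elliptic (Laplacian) smoothing of the interior grid above the shaft:
  # removes the cell folding the algebraic Coons blend produces near the
  # trochanteric saddle; boundaries and the P-Q interface row stay fixed
  ii <- rep(1:(nx - 1L), times = ny - j_s - 1L)
  jj <- rep((j_s + 1L):(ny - 1L), each = nx - 1L)
  ctr <- gid(ii, jj)
  nb <- cbind(gid(ii - 1L, jj), gid(ii + 1L, jj),
              gid(ii, jj - 1L), gid(ii, jj + 1L))
  n_smooth <- max(120L, as.integer(ny * ny / 15))
  for (it in seq_len(n_smooth)) {
    nodes[ctr, 1] <- (nodes[nb[, 1], 1] + nodes[nb[, 2], 1] +
                        nodes[nb[, 3], 1] + nodes[nb[, 4], 1]) / 4
    nodes[ctr, 2] <- (nodes[nb[, 1], 2] + nodes[nb[, 2], 2] +
                        nodes[nb[, 3], 2] + nodes[nb[, 4], 2]) / 4
  }

  quads <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L))
  nc <- max(1L, as.integer(round(spec$cortical_fraction * nx)))
  j_gap <- as.integer(round(spec$gap_top_fraction * j_s))
  in_gap <- quads$i >= nc & quads$i <= (nx - nc - 1L) & quads$j < j_gap
  quads <- quads[!in_gap, , drop = FALSE]
  fem_elems <- split_quads_adaptive(nodes,
                                    gid(quads$i, quads$j),
                                    gid(quads$i + 1L, quads$j),
                                    gid(quads$i + 1L, quads$j + 1L),
                                    gid(quads$i, quads$j + 1L))

  # side-plate: duplicate the shaft-trapezoid grid, sharing only the
  # lateral (i = 0) and medial (i = nx) columns with the femur
  nnode0 <- nrow(nodes)
  plate_map <- matrix(0L, nx + 1L, j_s + 1L)    # [i+1, j+1] -> node id
  extra <- list()
  nid <- nnode0
  for (j in 0:j_s) for (i in 0:nx) {
    if (i == 0L || i == nx) plate_map[i + 1L, j + 1L] <- gid(i, j)
    else {
      nid <- nid + 1L
      plate_map[i + 1L, j + 1L] <- nid
      extra[[length(extra) + 1L]] <- nodes[gid(i, j), ]
    }
  }
  nodes <- rbind(nodes, do.call(rbind, extra))
  pq <- expand.grid(i = 0:(nx - 1L), j = 0:(j_s - 1L))
  plate_elems <- split_quads_adaptive(nodes,
                                      plate_map[cbind(pq$i + 1L, pq$j + 1L)],
                                      plate_map[cbind(pq$i + 2L, pq$j + 1L)],
                                      plate_map[cbind(pq$i + 2L, pq$j + 2L)],
                                      plate_map[cbind(pq$i + 1L, pq$j + 2L)])

  elements <- rbind(fem_elems, plate_elems)
  region <- c(rep("FEMUR", nrow(fem_elems)),
              rep("SIDE_PLATE", nrow(plate_elems)))

  # boundary chains (pre-pruning ids)
  f_load <- min(1, spec$load_arc_deg / spec$head_arc_deg)
  i0 <- as.integer(round(nx * (1 - f_load) / 2))
  head_arc <- gid(i0:(nx - i0), ny)
  j_lo <- as.integer(round(spec$trochanter_span[1] * ny))
  j_hi <- as.integer(round(spec$trochanter_span[2] * ny))
  j_lo <- max(j_lo, j_s + 1L)
  troch_arc <- gid(0L, j_lo:j_hi)
  j_T <- max(1L, as.integer(round(j_s / 3)))
  left_edge <- gid(0L, 0:j_T)
  shared_lat <- gid(0L, 0:j_s)
  shared_med <- gid(nx, 0:j_s)
  bottom_fem <- gid(c(0:nc, (nx - nc):nx), 0L)
  bottom_plate <- plate_map[1L + setdiff(0:nx, c(0L, nx)), 1L]
  bottom <- c(sort(unique(bottom_fem)), bottom_plate)

  boundaries <- list(HEAD_ARC = head_arc, TROCHANTER_ARC = troch_arc,
                     BOTTOM_EDGE = bottom, LEFT_EDGE = left_edge,
                     SHARED_LATERAL = shared_lat, SHARED_MEDIAL = shared_med)
  landmarks <- c(P = gid(0L, j_s), Q = gid(nx, j_s),
                 R = gid(0L, 0L), S = gid(nx, 0L), T = gid(0L, j_T))

  # prune nodes orphaned by the medullary gap and remap everything
  used <- sort(unique(as.integer(elements)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  elements <- matrix(remap[elements], ncol = 3)
  boundaries <- lapply(boundaries, function(ch) {
    ch <- remap[ch]
    ch[ch > 0L]
  })
  landmarks <- stats::setNames(remap[landmarks], names(landmarks))
  nodes <- nodes[used, , drop = FALSE]

  bone_mesh(nodes, elements, region, boundaries = boundaries,
            thickness = c(FEMUR = spec$femur_thickness,
                          SIDE_PLATE = spec$plate_thickness),
            landmarks = landmarks)
}

#' Circular region-of-interest element mask
#'
#' @param mesh A [bone_mesh()].
#' @param center Circle centre (mm).
#' @param radius Circle radius (mm).
#' @param region Region restriction (default femur only).
#' @return Logical vector over elements: centroid inside the circle.
#' @export
roi_circle <- function(mesh, center, radius, region = "FEMUR") {
  ctr <- element_centroids(mesh)
  inside <- (ctr[, 1] - center[1])^2 + (ctr[, 2] - center[2])^2 <= radius^2
  inside & mesh$region %in% region
}

#' Default regions of interest on the stylised femur
#'
#' Four circular ROIs: femoral head centre (I), neck / Ward's triangle
#' region (II), medial calcar (III) and greater trochanter (IV).
#'
#' @param mesh A femur mesh from [generate_femur2d()].
#' @param spec The [femur2d_spec()] used to build it.
#' @return Named list of logical element masks.
#' @export
femur2d_rois <- function(mesh, spec = femur2d_spec()) {
  Ch <- spec$head_center
  hs <- spec$shaft_height
  list(
    I = roi_circle(mesh, Ch, spec$head_radius * 0.5),
    II = roi_circle(mesh, c(Ch[1] - 14, Ch[2] - 22), 9),
    III = roi_circle(mesh, c(spec$rs_distance + 12, hs + 6), 9),
    IV = roi_circle(mesh, c(2, hs + 24), 9)
  )
}

#' Closed-form remodelling equilibrium density of a uniformly stressed bar
#'
#' Setting the density rate to zero under uniaxial stress \eqn{\sigma} with
#' \eqn{U = \sigma^2 / (2 E(\rho))} and \eqn{E = M\rho^\gamma} gives
#' \deqn{\rho^* = (\sigma^2 / (2 M S_r))^{1/(\gamma + 1)}.}
#'
#' @param sigma Axial stress (MPa), > 0.
#' @param params A [material_params()].
#' @return Equilibrium density (g/cm^3).  If the unconstrained root lies
#'   outside `[rho_min, rho_max]` the clamped value is returned with
#'   attribute `clamped = TRUE`.
#' @examples
#' analytic_equilibrium_density(3)  # ~0.738 g/cm^3
#' @export
analytic_equilibrium_density <- function(sigma, params = material_params()) {
  stopifnot(sigma >= 0)
  rho <- (sigma^2 / (2 * params$M * params$S_r))^(1 / (params$gamma + 1))
  if (rho < params$rho_min || rho > params$rho_max) {
    out <- min(max(rho, params$rho_min), params$rho_max)
    attr(out, "clamped") <- TRUE
    return(out)
  }
  rho
}

#' Closed-form tip potential of an open-circuit axially strained bar
#'
#' One-dimensional reduction of the coupled law with zero free charge
#' (D = 0): a bar poled along its axis, grounded at the base and strained
#' axially by \eqn{\epsilon = \sigma / E(\rho)}, develops
#' \deqn{\varphi(tip) = (e_{33} / \beta_{33}) \epsilon L}
#' under the convention \eqn{E = -\nabla\varphi}.  The density scale
#' \eqn{\alpha(\rho)} cancels between coupling and permittivity.
#'
#' @param sigma_axial Axial stress (MPa).
#' @param length Bar length (mm).
#' @param rho Apparent density (g/cm^3).
#' @param params A [material_params()].
#' @return Tip potential (V), positive in tension.
#' @examples
#' # strain 1e-3 over 100 mm: ~1.7621 V
#' analytic_piezo_bar_potential(1e-3 * 3790, 100, 1.0)
#' @export
analytic_piezo_bar_potential <- function(sigma_axial, length, rho,
                                         params = material_params()) {
  eps <- sigma_axial / elastic_modulus(rho, params)
  (params$e33 / params$beta33) * eps * length
}
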