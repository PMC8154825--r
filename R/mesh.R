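# Tagged unstructured 2-D mesh container and validation.

REGION_LEVELS <- c("FEMUR", "SIDE_PLATE")
BOUNDARY_NAMES <- c("HEAD_ARC", "TROCHANTER_ARC", "BOTTOM_EDGE", "LEFT_EDGE",
                    "SHARED_LATERAL", "SHARED_MEDIAL", "TOP_EDGE", "RIGHT_EDGE")

#' Construct a tagged 2-D triangle mesh
#'
#' The working container of the simulator: linear triangles over a plane
#' domain, each element tagged `FEMUR` or `SIDE_PLATE`, plus named ordered
#' boundary node chains (femoral head arc, trochanter arc, clamped edges,
#' and the lateral/medial chains along which the side-plate is joined to
#' the femur).  Thickness is a per-region scalar used as a multiplier in
#' assembly, not a geometric dimension.
#'
#' @param nodes Numeric matrix n x 2 of node coordinates (mm).
#' @param elements Integer matrix ne x 3 of 1-based node indices,
#'   counter-clockwise.
#' @param region Character vector of length ne with values `"FEMUR"` or
#'   `"SIDE_PLATE"`.
#' @param boundaries Named list of integer vectors: ordered node chains.
#' @param thickness Named numeric vector of per-region thickness (mm),
#'   e.g. `c(FEMUR = 1, SIDE_PLATE = 0.1)`.
#' @param landmarks Optional named integer vector of landmark node ids
#'   (e.g. P, Q, R, S, T).
#' @param repair_orientation Repair clockwise triangles by swapping two
#'   nodes (with a warning) instead of leaving them for [validate_mesh()].
#' @return Object of class `bone_mesh`.
#' @export
bone_mesh <- function(nodes, elements, region,
                      boundaries = list(),
                      thickness = c(FEMUR = 1),
                      landmarks = NULL,
                      repair_orientation = FALSE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 2L) stop("nodes must be an n x 2 coordinate matrix")
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  if (ncol(elements) != 3L) stop("elements must be an ne x 3 connectivity matrix")
  region <- as.character(region)
  if (length(region) != nrow(elements))
    stop("region must tag every element exactly once")
  if (!all(region %in% REGION_LEVELS))
    stop("unknown region tag(s): ",
         paste(unique(setdiff(region, REGION_LEVELS)), collapse = ", "))
  if (anyNA(elements) || any(elements < 1L) || any(elements > nrow(nodes)))
    stop("element connectivity references nodes outside the mesh")
  if (!is.list(boundaries) ||
      (length(boundaries) && is.null(names(boundaries))))
    stop("boundaries must be a named list of node chains")
  boundaries <- lapply(boundaries, as.integer)
  mesh <- structure(list(nodes = nodes, elements = elements,
                         region = region, boundaries = boundaries,
                         thickness = thickness, landmarks = landmarks),
                    class = "bone_mesh")
  if (repair_orientation) {
    a <- element_areas(mesh)
    flip <- which(a < 0)
    if (length(flip)) {
      warning("repaired orientation of ", length(flip),
              " clockwise triangle(s)")
      mesh$elements[flip, 2:3] <- mesh$elements[flip, 3:2]
    }
  }
  mesh
}

#' @export
print.bone_mesh <- function(x, ...) {
  cat("<bone_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$elements),
      " triangles (", sum(x$region == "FEMUR"), " femur / ",
      sum(x$region == "SIDE_PLATE"), " side-plate)\n", sep = "")
  if (length(x$boundaries))
    cat("  boundaries:", paste(names(x$boundaries), collapse = ", "), "\n")
  cat("  thickness:",
      paste(sprintf("%s=%g mm", names(x$thickness), x$thickness),
            collapse = ", "), "\n")
  invisible(x)
}

#' Signed element areas
#'
#' @param mesh A [bone_mesh()].
#' @return Numeric vector of signed areas (mm^2); positive for
#'   counter-clockwise triangles.
#' @export
element_areas <- function(mesh) {
  n <- mesh$nodes
  e <- mesh$elements
  x1 <- n[e[, 1], 1]; y1 <- n[e[, 1], 2]
  x2 <- n[e[, 2], 1]; y2 <- n[e[, 2], 2]
  x3 <- n[e[, 3], 1]; y3 <- n[e[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

#' Element centroids
#' @param mesh A [bone_mesh()].
#' @return ne x 2 matrix of centroid coordinates (mm).
#' @export
element_centroids <- function(mesh) {
  n <- mesh$nodes
  e <- mesh$elements
  cbind((n[e[, 1], 1] + n[e[, 2], 1] + n[e[, 3], 1]) / 3,
        (n[e[, 1], 2] + n[e[, 2], 2] + n[e[, 3], 2]) / 3)
}

element_thickness <- function(mesh) {
  th <- mesh$thickness[mesh$region]
  if (anyNA(th)) stop("thickness missing for region(s): ",
                      paste(unique(mesh$region[is.na(th)]), collapse = ", "))
  unname(th)
}

# Resolve a boundary segment given by name or by an explicit node chain.
resolve_segment <- function(mesh, segment) {
  if (is.character(segment) && length(segment) == 1L) {
    chain <- mesh$boundaries[[segment]]
    if (is.null(chain)) stop("mesh has no boundary segment named '", segment, "'")
    return(chain)
  }
  as.integer(segment)
}

#' Validate a mesh against the container invariants
#'
#' Report-based validation: checks region tags, element orientation
#' (positive signed area), degenerate and duplicate nodes (per region, since
#' the side-plate deliberately overlays the femur shaft geometrically),
#' dangling boundary references, positive thickness, and that femur and
#' side-plate share nodes only along the `SHARED_LATERAL` / `SHARED_MEDIAL`
#' chains.
#'
#' @param mesh A [bone_mesh()].
#' @param tol Coordinate tolerance (mm) for duplicate-node detection.
#' @return A data frame with columns `check`, `ids` (comma-separated offender
#'   ids), `message`; zero rows means the mesh is valid.
#' @export
validate_mesh <- function(mesh, tol = 1e-9) {
  rep <- list()
  add <- function(check, ids, message)
    rep[[length(rep) + 1L]] <<- data.frame(
      check = check, ids = paste(ids, collapse = ","),
      message = message, stringsAsFactors = FALSE)

  a <- element_areas(mesh)
  bad <- which(a <= 0)
  if (length(bad))
    add("element_orientation", bad,
        "triangles with non-positive signed area (inverted or degenerate)")

  th <- mesh$thickness[unique(mesh$region)]
  if (any(is.na(th) | th <= 0))
    add("thickness", names(mesh$thickness)[is.na(mesh$thickness) | mesh$thickness <= 0],
        "thickness must be defined and > 0 for every region in use")

  used <- sort(unique(as.integer(mesh$elements)))
  dangling <- setdiff(seq_len(nrow(mesh$nodes)), used)
  if (length(dangling))
    add("unused_nodes", dangling, "nodes not referenced by any element")

  # duplicate coordinates within one region's node set
  for (rg in intersect(REGION_LEVELS, unique(mesh$region))) {
    ids <- sort(unique(as.integer(mesh$elements[mesh$region == rg, ])))
    key <- paste(round(mesh$nodes[ids, 1] / tol), round(mesh$nodes[ids, 2] / tol))
    dup <- ids[duplicated(key) | duplicated(key, fromLast = TRUE)]
    if (length(dup))
      add("duplicate_nodes", dup,
          paste0("coincident node coordinates within region ", rg))
  }

  for (nm in names(mesh$boundaries)) {
    chain <- mesh$boundaries[[nm]]
    bad <- chain[chain < 1L | chain > nrow(mesh$nodes)]
    if (length(bad))
      add("boundary_reference", bad,
          paste0("boundary '", nm, "' references nodes outside the mesh"))
  }

  if (any(mesh$region == "SIDE_PLATE")) {
    fn <- unique(as.integer(mesh$elements[mesh$region == "FEMUR", ]))
    pn <- unique(as.integer(mesh$elements[mesh$region == "SIDE_PLATE", ]))
    shared <- intersect(fn, pn)
    allowed <- unique(c(mesh$boundaries$SHARED_LATERAL,
                        mesh$boundaries$SHARED_MEDIAL))
    illegal <- setdiff(shared, allowed)
    if (length(illegal))
      add("illegal_region_sharing", illegal,
          "femur and side-plate share nodes outside the SHARED_* chains")
  }

  if (length(rep)) do.call(rbind, rep) else
    data.frame(check = character(), ids = character(),
               message = character(), stringsAsFactors = FALSE)
}

#' Total in-plane area of the mesh
#'
#' Sum of signed element areas; equals the polygon area of the domain
#' boundary for a valid tessellation.
#'
#' @param mesh A [bone_mesh()].
#' @param region Optional region restriction.
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh, region = NULL) {
  a <- element_areas(mesh)
  if (!is.null(region)) a <- a[mesh$region %in% region]
  sum(a)
}

# Arc lengths along an ordered node chain; returns cumulative lengths
# starting at 0 and the total.
chain_arclength <- function(mesh, chain) {
  xy <- mesh$nodes[chain, , drop = FALSE]
  d <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  s <- c(0, cumsum(d))
  list(s = s, total = s[length(s)])
}
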