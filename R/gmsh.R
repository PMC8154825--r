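# Gmsh MSH v2 ASCII reader/writer.
#
# Only the v2.x ASCII dialect is supported (deterministic parsing; matches
# the Salome -> Gmsh -> solver toolchain the model descends from).  v4 files
# are rejected with a clear message.

msh_sections <- function(lines) {
  starts <- grep("^\\$[A-Za-z]", lines)
  sec <- list()
  i <- 1L
  while (i <= length(starts)) {
    name <- sub("^\\$", "", lines[starts[i]])
    end <- grep(paste0("^\\$End", name, "\\s*$"), lines)
    end <- end[end > starts[i]][1]
    if (is.na(end)) stop("malformed MSH file: unterminated section $", name)
    sec[[name]] <- lines[(starts[i] + 1L):(end - 1L)]
    i <- i + 2L
  }
  sec
}

split_fields <- function(x) strsplit(trimws(x), "\\s+")

#' Read a Gmsh MSH v2 ASCII mesh
#'
#' Reads nodes, elements and physical groups.  Triangles (3-node, and 6-node
#' reduced to their corner nodes) become mesh elements; physical line
#' elements become named boundary chains (ordered by walking the segment
#' adjacency).  One-tetrahedron-thick slice meshes (the plane-strain slice
#' trick used when a 3-D code cannot mesh a 2-D domain) are accepted and
#' flattened to the mid-plane triangulation: nodes sharing (x, y) within
#' `flatten_tol` are merged per region and each tetrahedron projects to its
#' base triangle.
#'
#' @param path Path to a `.msh` file.
#' @param tag_map Named character vector mapping physical group ids (as
#'   character) to region/boundary names, e.g.
#'   `c("1" = "FEMUR", "2" = "HEAD_ARC")`.  When `NULL`, the `$PhysicalNames`
#'   section must be present and its names are used directly.
#' @param thickness Per-region thickness (mm).
#' @param flatten_tol Coordinate tolerance for slice flattening (mm).
#' @return A [bone_mesh()].
#' @export
read_gmsh_mesh <- function(path, tag_map = NULL,
                           thickness = c(FEMUR = 1, SIDE_PLATE = 0.1),
                           flatten_tol = 1e-6) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sec <- msh_sections(lines)

  if (is.null(sec$MeshFormat)) stop("not an MSH file (no $MeshFormat): ", path)
  fmt <- split_fields(sec$MeshFormat[1])[[1]]
  ver <- as.numeric(fmt[1])
  if (is.na(ver) || ver >= 3)
    stop("unsupported MSH format version ", fmt[1],
         ": only the v2 ASCII dialect is supported (export with gmsh -format msh2)")
  if (fmt[2] != "0") stop("binary MSH files are not supported; export ASCII")

  phys <- character()
  if (!is.null(sec$PhysicalNames)) {
    rows <- split_fields(sec$PhysicalNames[-1])
    for (r in rows) {
      if (length(r) < 3) next
      phys[r[2]] <- gsub('"', "", paste(r[-(1:2)], collapse = " "))
    }
  }
  if (!is.null(tag_map)) phys[names(tag_map)] <- unname(tag_map)
  if (!length(phys))
    stop("no physical names available: supply tag_map or a $PhysicalNames section")

  if (is.null(sec$Nodes) || is.null(sec$Elements))
    stop("malformed MSH file: missing $Nodes or $Elements")
  nn <- as.integer(sec$Nodes[1])
  ndat <- scan(text = paste(sec$Nodes[-1], collapse = "\n"), quiet = TRUE)
  ndat <- matrix(ndat, ncol = 4, byrow = TRUE)
  if (nrow(ndat) != nn) stop("malformed $Nodes section")
  node_id <- as.integer(ndat[, 1])
  id2row <- integer(max(node_id))
  id2row[node_id] <- seq_len(nn)
  coords3 <- ndat[, 2:4, drop = FALSE]

  erows <- split_fields(sec$Elements[-1])
  tris <- list(); tri_tag <- integer()
  tets <- list(); tet_tag <- integer()
  lines2 <- list(); line_tag <- integer()
  untagged <- integer()
  for (r in erows) {
    v <- as.integer(r)
    id <- v[1]; type <- v[2]; ntags <- v[3]
    tags <- if (ntags > 0) v[4:(3 + ntags)] else integer()
    nodes <- v[(4 + ntags):length(v)]
    ptag <- if (length(tags)) tags[1] else NA_integer_
    if (type == 15L) next                     # point elements carry no fields we use
    if (is.na(ptag) || ptag == 0L) { untagged <- c(untagged, id); next }
    if (type == 2L) { tris[[length(tris) + 1L]] <- nodes; tri_tag <- c(tri_tag, ptag) }
    else if (type == 9L) { tris[[length(tris) + 1L]] <- nodes[1:3]; tri_tag <- c(tri_tag, ptag) }
    else if (type == 4L) { tets[[length(tets) + 1L]] <- nodes; tet_tag <- c(tet_tag, ptag) }
    else if (type == 11L) { tets[[length(tets) + 1L]] <- nodes[1:4]; tet_tag <- c(tet_tag, ptag) }
    else if (type == 1L || type == 8L) { lines2[[length(lines2) + 1L]] <- nodes[1:2]; line_tag <- c(line_tag, ptag) }
    else stop("unsupported element type ", type, " in ", path)
  }
  if (length(untagged))
    stop("untagged element(s) in ", path, ": ids ",
         paste(utils::head(untagged, 20), collapse = ", "),
         if (length(untagged) > 20) ", ..." else "")

  lookup_name <- function(tags, what) {
    nm <- phys[as.character(tags)]
    miss <- unique(tags[is.na(nm)])
    if (length(miss))
      stop("physical group id(s) ", paste(miss, collapse = ", "),
           " for ", what, " absent from tag_map/$PhysicalNames")
    nm
  }

  if (length(tets)) {
    flat <- flatten_tets(coords3, id2row, tets, lookup_name(tet_tag, "volumes"),
                         lines2, lookup_name(line_tag, "lines"), flatten_tol)
    nodes <- flat$nodes; elements <- flat$elements
    region <- flat$region; chains <- flat$chains
  } else {
    if (!length(tris)) stop("mesh contains no surface elements")
    nodes <- coords3[, 1:2, drop = FALSE]
    elements <- matrix(id2row[unlist(tris)], ncol = 3, byrow = TRUE)
    region <- unname(lookup_name(tri_tag, "surfaces"))
    chains <- list()
    if (length(lines2)) {
      segs <- matrix(id2row[unlist(lines2)], ncol = 2, byrow = TRUE)
      nm <- lookup_name(line_tag, "lines")
      for (u in unique(nm))
        chains[[u]] <- order_chain(segs[nm == u, , drop = FALSE])
    }
  }

  bad_region <- setdiff(unique(region), REGION_LEVELS)
  if (length(bad_region))
    stop("surface physical name(s) not a known region: ",
         paste(bad_region, collapse = ", "))

  bone_mesh(nodes, elements, region, boundaries = chains,
            thickness = thickness, repair_orientation = TRUE)
}

# Order loose 2-node segments into one node chain.  Open chains start at a
# degree-1 endpoint (smallest node id for determinism); closed loops start
# at their smallest node id.
order_chain <- function(segs) {
  if (nrow(segs) == 0L) return(integer())
  nodes <- sort(unique(as.integer(segs)))
  adj <- lapply(stats::setNames(nodes, nodes), function(...) integer())
  for (i in seq_len(nrow(segs))) {
    a <- as.character(segs[i, 1]); b <- as.character(segs[i, 2])
    adj[[a]] <- c(adj[[a]], segs[i, 2])
    adj[[b]] <- c(adj[[b]], segs[i, 1])
  }
  deg <- vapply(adj, length, integer(1))
  ends <- nodes[deg == 1L]
  start <- if (length(ends)) min(ends) else min(nodes)
  chain <- start
  prev <- -1L
  repeat {
    nb <- adj[[as.character(chain[length(chain)])]]
    nxt <- nb[nb != prev]
    if (!length(nxt)) break
    nxt <- nxt[1]
    if (nxt %in% chain) break  # loop closed
    prev <- chain[length(chain)]
    chain <- c(chain, nxt)
    if (length(chain) > length(nodes)) stop("boundary chain is not a simple path")
  }
  chain
}

# Flatten a one-element-thick tetrahedral slice mesh to its 2-D mid-plane
# triangulation (per-region node merge on (x, y)).
flatten_tets <- function(coords3, id2row, tets, tet_region,
                         lines2, line_names, tol) {
  nraw <- nrow(coords3)
  key <- paste(round(coords3[, 1] / tol), round(coords3[, 2] / tol))
  merged <- match(key, key)              # representative raw row per (x,y)
  newid <- integer(nraw)
  reps <- sort(unique(merged))
  newid[reps] <- seq_along(reps)
  newid <- newid[merged]
  nodes <- coords3[reps, 1:2, drop = FALSE]

  tri_list <- vector("list", length(tets))
  for (i in seq_along(tets)) {
    tri <- unique(newid[id2row[tets[[i]]]])
    if (length(tri) != 3L)
      stop("tetrahedron ", i, " does not project to a triangle; ",
           "the mesh is not a one-element-thick slice")
    tri_list[[i]] <- sort(tri)
  }
  tri_mat <- do.call(rbind, tri_list)
  keykey <- paste(tri_mat[, 1], tri_mat[, 2], tri_mat[, 3], tet_region)
  keep <- !duplicated(keykey)
  elements <- tri_mat[keep, , drop = FALSE]
  region <- tet_region[keep]

  chains <- list()
  if (length(lines2)) {
    segs <- matrix(newid[id2row[unlist(lines2)]], ncol = 2, byrow = TRUE)
    ok <- segs[, 1] != segs[, 2]
    segs <- segs[ok, , drop = FALSE]
    nm <- line_names[ok]
    skey <- paste(pmin(segs[, 1], segs[, 2]), pmax(segs[, 1], segs[, 2]), nm)
    keep <- !duplicated(skey)
    segs <- segs[keep, , drop = FALSE]; nm <- nm[keep]
    for (u in unique(nm))
      chains[[u]] <- order_chain(segs[nm == u, , drop = FALSE])
  }
  list(nodes = nodes, elements = elements, region = region, chains = chains)
}

#' Write a mesh as Gmsh MSH v2 ASCII
#'
#' Regions and boundary chains are written as physical groups
#' (`$PhysicalNames`), so [read_gmsh_mesh()] round-trips the mesh.
#'
#' @param mesh A [bone_mesh()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmsh_mesh <- function(mesh, path) {
  region_names <- intersect(REGION_LEVELS, unique(mesh$region))
  bnames <- names(mesh$boundaries)
  ids <- stats::setNames(seq_along(c(region_names, bnames)),
                         c(region_names, bnames))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "2.2 0 8", "$EndMeshFormat")
  w("$PhysicalNames", as.character(length(ids)))
  for (nm in region_names) w(sprintf('2 %d "%s"', ids[[nm]], nm))
  for (nm in bnames) w(sprintf('1 %d "%s"', ids[[nm]], nm))
  w("$EndPhysicalNames")
  n <- nrow(mesh$nodes)
  w("$Nodes", as.character(n))
  w(sprintf("%d %.17g %.17g 0", seq_len(n), mesh$nodes[, 1], mesh$nodes[, 2]))
  w("$EndNodes")
  eid <- 0L
  elem_lines <- character()
  for (nm in bnames) {
    chain <- mesh$boundaries[[nm]]
    if (length(chain) < 2L) next
    for (i in seq_len(length(chain) - 1L)) {
      eid <- eid + 1L
      elem_lines <- c(elem_lines,
                      sprintf("%d 1 2 %d %d %d %d", eid, ids[[nm]], ids[[nm]],
                              chain[i], chain[i + 1L]))
    }
  }
  ne <- nrow(mesh$elements)
  rid <- unname(ids[mesh$region])
  tri_lines <- sprintf("%d 2 2 %d %d %d %d %d", eid + seq_len(ne), rid, rid,
                       mesh$elements[, 1], mesh$elements[, 2], mesh$elements[, 3])
  eid <- eid + ne
  w("$Elements", as.character(eid), elem_lines, tri_lines, "$EndElements")
  invisible(path)
}
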