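# Result frames and legacy VTK (ASCII) time-series output for Paraview.

#' Construct a result frame
#'
#' One snapshot of a remodelling run: nodal displacement (and optionally
#' electric potential) with elementwise density and strain energy density.
#'
#' @param time Simulation time in days.
#' @param displacement n x 2 matrix of nodal displacements (mm).
#' @param density Elementwise apparent density (g/cm^3); `NA` on
#'   non-remodelling (side-plate) elements.
#' @param sed Elementwise strain energy density (MPa); `NA` allowed.
#' @param potential Optional nodal electric potential (V).
#' @return Object of class `result_frame`.
#' @export
result_frame <- function(time, displacement, density, sed = NULL,
                         potential = NULL) {
  displacement <- as.matrix(displacement)
  if (ncol(displacement) != 2L) stop("displacement must be n x 2")
  structure(list(time = time, displacement = displacement,
                 density = as.numeric(density),
                 sed = if (is.null(sed)) NULL else as.numeric(sed),
                 potential = if (is.null(potential)) NULL else as.numeric(potential)),
            class = "result_frame")
}

check_frame <- function(mesh, frame) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  if (nrow(frame$displacement) != n)
    stop("frame displacement has ", nrow(frame$displacement),
         " rows but the mesh has ", n, " nodes")
  if (length(frame$density) != ne)
    stop("frame density has length ", length(frame$density),
         " but the mesh has ", ne, " elements")
  if (!is.null(frame$sed) && length(frame$sed) != ne)
    stop("frame SED length does not match the element count")
  if (!is.null(frame$potential) && length(frame$potential) != n)
    stop("frame potential length does not match the node count")
  invisible(frame)
}

fmt_num <- function(x) {
  x[is.na(x)] <- NaN
  sprintf("%.12g", x)
}

write_vtk_frame <- function(mesh, frame, path) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("# vtk DataFile Version 3.0",
    sprintf("piezobone result frame t=%g day", frame$time),
    "ASCII", "DATASET UNSTRUCTURED_GRID")
  w(sprintf("POINTS %d double", n))
  w(paste(fmt_num(mesh$nodes[, 1]), fmt_num(mesh$nodes[, 2]), "0"))
  w(sprintf("CELLS %d %d", ne, 4L * ne))
  w(paste("3", mesh$elements[, 1] - 1L, mesh$elements[, 2] - 1L,
          mesh$elements[, 3] - 1L))
  w(sprintf("CELL_TYPES %d", ne))
  w(rep("5", ne))
  w(sprintf("POINT_DATA %d", n))
  w("VECTORS displacement double")
  w(paste(fmt_num(frame$displacement[, 1]), fmt_num(frame$displacement[, 2]), "0"))
  if (!is.null(frame$potential)) {
    w("SCALARS potential double 1", "LOOKUP_TABLE default")
    w(fmt_num(frame$potential))
  }
  w(sprintf("CELL_DATA %d", ne))
  w("SCALARS density double 1", "LOOKUP_TABLE default")
  w(fmt_num(frame$density))
  w("SCALARS region int 1", "LOOKUP_TABLE default")
  w(as.character(as.integer(mesh$region == "SIDE_PLATE")))
  if (!is.null(frame$sed)) {
    w("SCALARS sed double 1", "LOOKUP_TABLE default")
    w(fmt_num(frame$sed))
  }
  invisible(path)
}

#' Write a time series of result frames as legacy VTK files
#'
#' One `.vtk` file per frame (cell data: density, SED, region; point data:
#' displacement, potential) plus a JSON manifest mapping frame index to time
#' in days and filename.
#'
#' @param mesh A [bone_mesh()].
#' @param frames Non-empty list of [result_frame()] objects.
#' @param dir Output directory (created if needed).
#' @param basename Stem for the frame files.
#' @return Character vector of the files written (frames + manifest),
#'   invisibly.
#' @export
write_result_series <- function(mesh, frames, dir, basename = "frame") {
  if (!length(frames)) stop("frames must be a non-empty list of result frames")
  if (inherits(frames, "result_frame")) frames <- list(frames)
  for (f in frames) check_frame(mesh, f)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(length(frames))
  for (i in seq_along(frames)) {
    files[i] <- sprintf("%s_%03d.vtk", basename, i - 1L)
    write_vtk_frame(mesh, frames[[i]], file.path(dir, files[i]))
  }
  manifest <- list(frames = lapply(seq_along(frames), function(i)
    list(index = i - 1L, time_days = frames[[i]]$time, file = files[i])))
  mpath <- file.path(dir, paste0(basename, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(file.path(dir, files), mpath))
}

# Minimal legacy-VTK reader for round-trip checks of files written by
# write_vtk_frame (not a general VTK parser).
read_vtk_frame <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks_after <- function(i, count) {
    vals <- numeric(0)
    j <- i + 1L
    while (length(vals) < count) {
      vals <- c(vals, scan(text = lines[j], quiet = TRUE))
      j <- j + 1L
    }
    vals
  }
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- matrix(toks_after(ip, 3L * n), ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  ne <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cells <- matrix(as.integer(toks_after(ic, 4L * ne)), ncol = 4, byrow = TRUE)
  out <- list(points = pts[, 1:2, drop = FALSE],
              elements = cells[, 2:4, drop = FALSE] + 1L)
  grab_scalar <- function(name, count) {
    i <- grep(paste0("^SCALARS ", name, " "), lines)
    if (!length(i)) return(NULL)
    toks_after(i[1] + 1L, count)   # skip LOOKUP_TABLE line
  }
  iv <- grep("^VECTORS displacement", lines)
  if (length(iv)) {
    disp <- matrix(toks_after(iv[1], 3L * n), ncol = 3, byrow = TRUE)
    out$displacement <- disp[, 1:2, drop = FALSE]
  }
  out$potential <- grab_scalar("potential", n)
  out$density <- grab_scalar("density", ne)
  out$sed <- grab_scalar("sed", ne)
  out
}
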