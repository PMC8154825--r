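# Configuration-driven entry points tying the pipeline together with
# logging and provenance.

#' Load and resolve a run configuration
#'
#' Reads a YAML or JSON configuration (by file extension) and fills in
#' defaults.  Sections: `mesh` (either `file` + optional `tag_map` or
#' `fixture` = `"bar"`/`"femur2d"` with its arguments), `material`
#' (overrides of [material_params()]), `schedule`
#' (fields of [remodel_schedule()]), `model` (`"elastic"`/`"piezo"`),
#' `stimulation`, `initial_density` (scalar or list for sweeps), `frames`
#' (days), `rois` (list of `{name, cx, cy, r}`), `output` (directory),
#' `seed` (logged but unused: the method is deterministic).
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or a list.
#' @return Resolved configuration list of class `run_config`.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    ext <- tolower(tools::file_ext(config))
    cfg <- switch(ext,
      yaml = , yml = yaml::read_yaml(config),
      json = jsonlite::read_json(config, simplifyVector = TRUE),
      stop("unsupported config format '.", ext, "' (use YAML or JSON)"))
    cfg$config_path <- normalizePath(config)
  } else if (is.list(config)) cfg <- config
  else stop("config must be a file path or a list")

  cfg$model <- cfg$model %||% "elastic"
  if (!cfg$model %in% c("elastic", "piezo"))
    stop("model must be 'elastic' or 'piezo'")
  cfg$stimulation <- isTRUE(cfg$stimulation)
  cfg$initial_density <- cfg$initial_density %||% 0.8
  cfg$frames <- cfg$frames %||% c(0, 150, 300)
  cfg$output <- cfg$output %||% "piezobone_run"
  cfg$mesh <- cfg$mesh %||% list(fixture = "femur2d")
  structure(cfg, class = c("run_config", "list"))
}

resolve_config_material <- function(cfg) {
  do.call(material_params, as.list(cfg$material %||% list()))
}

resolve_config_schedule <- function(cfg) {
  sc <- as.list(cfg$schedule %||% list())
  if (!is.null(sc$load_cases)) sc$load_cases <- as.data.frame(sc$load_cases)
  do.call(remodel_schedule, sc)
}

resolve_config_mesh <- function(cfg) {
  m <- cfg$mesh
  if (!is.null(m$file)) {
    tag_map <- if (!is.null(m$tag_map)) unlist(m$tag_map) else NULL
    return(read_gmsh_mesh(m$file, tag_map = tag_map))
  }
  fixture <- m$fixture %||% "femur2d"
  args <- m[setdiff(names(m), c("fixture", "file", "tag_map"))]
  switch(fixture,
    bar = do.call(generate_bar_mesh, args),
    femur2d = generate_femur2d(do.call(femur2d_spec, args)),
    stop("unknown fixture kind: ", fixture))
}

resolve_config_rois <- function(cfg, mesh) {
  if (is.null(cfg$rois)) {
    if (!is.null(cfg$mesh$fixture) && cfg$mesh$fixture == "femur2d") {
      sp <- do.call(femur2d_spec,
                    cfg$mesh[setdiff(names(cfg$mesh), c("fixture", "file", "tag_map"))])
      return(femur2d_rois(mesh, sp))
    }
    return(list())
  }
  rois <- list()
  for (r in cfg$rois)
    rois[[r$name]] <- roi_circle(mesh, c(r$cx, r$cy), r$r)
  rois
}

content_hash <- function(path) unname(tools::md5sum(path))

write_run_log <- function(dir, lines) {
  cat(paste0(lines, "\n"), file = file.path(dir, "run.log"),
      sep = "", append = TRUE)
}

#' Run one remodelling simulation from a configuration
#'
#' Resolves the configuration, runs [run_simulation()], and writes to the
#' output directory: result frames (legacy VTK + manifest), the per-step
#' trace as CSV, a copy of the resolved configuration, and a run log with
#' content hashes and a density summary.
#'
#' @param config Path or list, see [load_run_config()].
#' @param quiet Suppress progress messages.
#' @return The [run_simulation()] result, invisibly, with attribute
#'   `output_dir`.
#' @export
cmd_run <- function(config, quiet = FALSE) {
  cfg <- load_run_config(config)
  params <- resolve_config_material(cfg)
  schedule <- resolve_config_schedule(cfg)
  rho0 <- cfg$initial_density
  if (length(rho0) != 1L)
    stop("cmd_run takes a scalar initial_density; use cmd_sweep for lists")
  if (rho0 < params$rho_min || rho0 > params$rho_max)
    stop(sprintf("initial density %g outside the admissible bounds [%g, %g] g/cm^3",
                 rho0, params$rho_min, params$rho_max))
  mesh <- resolve_config_mesh(cfg)
  rois <- resolve_config_rois(cfg, mesh)

  dir.create(cfg$output, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  # programmatic configs may override the constraint sets (args to
  # boundary_conditions) and supply raw load vectors (or a function of the
  # mesh building them), e.g. for bar benchmarks
  bcs <- do.call(boundary_conditions, c(list(mesh), as.list(cfg$bcs %||% list())))
  lv <- cfg$load_vectors
  if (is.function(lv)) lv <- lv(mesh)
  run <- run_simulation(mesh, params, schedule, rho0,
                        model = cfg$model, stimulation = cfg$stimulation,
                        bcs = bcs, frame_times = cfg$frames, rois = rois,
                        load_vectors = lv)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  utils::write.csv(run$trace, file.path(cfg$output, "trace.csv"),
                   row.names = FALSE)
  if (length(run$frames))
    write_result_series(mesh, run$frames, cfg$output)
  resolved <- unclass(cfg)
  # drop programmatic-only entries that have no YAML representation
  resolved <- resolved[!vapply(resolved, is.function, logical(1))]
  yaml::write_yaml(resolved, file.path(cfg$output, "resolved_config.yaml"))
  log <- c(
    sprintf("piezobone run: model=%s stimulation=%s", cfg$model, cfg$stimulation),
    sprintf("config hash: %s",
            if (!is.null(cfg$config_path)) content_hash(cfg$config_path)
            else content_hash(file.path(cfg$output, "resolved_config.yaml"))),
    if (!is.null(cfg$mesh$file)) sprintf("mesh hash: %s", content_hash(cfg$mesh$file)),
    sprintf("seed (logged, unused - deterministic method): %s",
            cfg$seed %||% "none"),
    sprintf("steps: %d (dt = %g day), elapsed %.1f s", nrow(run$trace),
            schedule$dt, elapsed),
    sprintf("final density: avg %.4f, range [%.4f, %.4f] g/cm^3",
            average_density(run$density, mesh), min(run$density),
            max(run$density)))
  write_run_log(cfg$output, log)
  if (!quiet) message(paste(log, collapse = "\n"))
  attr(run, "output_dir") <- cfg$output
  invisible(run)
}

#' Sweep over initial densities
#'
#' One run per initial density value; writes a combined CSV of the
#' average-density traces and the pairwise difference summaries of the
#' final fields.
#'
#' @param config Path or list, see [load_run_config()].
#' @param rho0_list Initial density values (g/cm^3); defaults to
#'   `initial_density` from the configuration.
#' @param quiet Suppress messages.
#' @return Named list of [run_simulation()] results, invisibly.
#' @export
cmd_sweep <- function(config, rho0_list = NULL, quiet = FALSE) {
  cfg <- load_run_config(config)
  rho0_list <- rho0_list %||% unlist(cfg$initial_density)
  if (!length(rho0_list)) stop("rho0_list must be nonempty")
  runs <- list()
  combined <- NULL
  outdir <- cfg$output
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (r0 in rho0_list) {
    sub <- utils::modifyList(unclass(cfg), list(
      initial_density = r0, output = file.path(outdir, sprintf("rho0_%g", r0))))
    run <- cmd_run(sub, quiet = quiet)
    runs[[sprintf("%g", r0)]] <- run
    tr <- run$trace[, c("day", "avg_density")]
    names(tr)[2] <- sprintf("avg_density_rho0_%g", r0)
    combined <- if (is.null(combined)) tr else merge(combined, tr, by = "day")
  }
  utils::write.csv(combined, file.path(outdir, "sweep_traces.csv"),
                   row.names = FALSE)
  if (length(runs) > 1L) {
    nm <- names(runs)
    diffs <- list()
    for (a in seq_along(runs)) for (b in seq_along(runs)) if (a < b) {
      d <- density_difference(runs[[a]]$density, runs[[b]]$density)
      diffs[[length(diffs) + 1L]] <- data.frame(
        rho0_a = nm[a], rho0_b = nm[b],
        mean_abs_diff = mean(abs(d)), max_abs_diff = max(abs(d)))
    }
    utils::write.csv(do.call(rbind, diffs),
                     file.path(outdir, "sweep_final_differences.csv"),
                     row.names = FALSE)
  }
  invisible(runs)
}

#' Validate a predicted density field against reference points
#'
#' Computes RMS error and mean deviation of a run's final density field
#' against a reference CSV (`x_mm, y_mm, density_gcm3` or `hu`), prints
#' them, and writes them as JSON.
#'
#' @param run A [run_simulation()]/[cmd_run()] result (its mesh is used).
#' @param reference Path to the reference CSV, or a data frame.
#' @param out Optional JSON output path.
#' @param constants A [calibration_constants()].
#' @return The metric list from [rms_and_mean_deviation()], invisibly.
#' @export
cmd_validate <- function(run, reference, out = NULL,
                         constants = calibration_constants()) {
  stopifnot(inherits(run, "remodel_run"))
  ref <- if (is.character(reference)) {
    if (!file.exists(reference)) stop("reference file not found: ", reference)
    utils::read.csv(reference)
  } else as.data.frame(reference)
  m <- rms_and_mean_deviation(run$density, run$mesh, ref, constants)
  message(sprintf("RMS error: %.4f g/cm^3; mean deviation: %.4f g/cm^3 (n = %d)",
                  m$rms, m$mean_deviation, m$n))
  if (!is.null(out))
    jsonlite::write_json(list(rms_gcm3 = m$rms,
                              mean_deviation_gcm3 = m$mean_deviation,
                              n_points = m$n),
                         out, auto_unbox = TRUE, digits = NA)
  invisible(m)
}
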