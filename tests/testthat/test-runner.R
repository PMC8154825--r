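bar_config <- function(outdir, ...) {
  m <- generate_bar_mesh(50, 10, 4, 2)
  st <- bar_axial_setup(m, 3)
  utils::modifyList(list(
    mesh = list(fixture = "bar", length = 50, width = 10, nx = 4, ny = 2),
    bcs = list(fixed_vertical = "BOTTOM_EDGE",
               fixed_both = m$boundaries$BOTTOM_EDGE[1],
               grounded = NULL),
    load_vectors = function(mesh) list(
      uniform_traction_vector(mesh, "TOP_EDGE", 3 * 10, 0, "up")),
    schedule = list(dt = 0.1, t_remodel = 10),
    frames = c(0, 10),
    initial_density = 0.8,
    output = outdir
  ), list(...))
}

test_that("cmd_run writes traces, frames, config and log", {
  outdir <- file.path(tempfile(), "run")
  run <- cmd_run(bar_config(outdir), quiet = TRUE)
  expect_s3_class(run, "remodel_run")
  # 10 days at dt = 0.1: 100 trace rows
  tr <- utils::read.csv(file.path(outdir, "trace.csv"))
  expect_equal(nrow(tr), 100)
  expect_true(file.exists(file.path(outdir, "resolved_config.yaml")))
  expect_true(file.exists(file.path(outdir, "run.log")))
  expect_true(file.exists(file.path(outdir, "frame_manifest.json")))
  log <- readLines(file.path(outdir, "run.log"))
  expect_true(any(grepl("hash", log)))
})

test_that("degenerate coupling reproduces the elastic trace", {
  out1 <- file.path(tempfile(), "elastic")
  out2 <- file.path(tempfile(), "piezo0")
  r1 <- cmd_run(bar_config(out1, model = "elastic"), quiet = TRUE)
  cfg2 <- bar_config(out2, model = "piezo",
                     material = list(e31 = 0, e33 = 0, e15 = 0),
                     schedule = list(dt = 0.1, t_remodel = 10, charge = 0))
  cfg2$bcs$grounded <- "BOTTOM_EDGE"
  r2 <- cmd_run(cfg2, quiet = TRUE)
  expect_equal(r2$density, r1$density, tolerance = 1e-12)
  expect_equal(r2$trace$avg_density, r1$trace$avg_density, tolerance = 1e-12)
})

test_that("invalid initial density is rejected citing the bounds", {
  expect_error(cmd_run(bar_config(tempfile(), initial_density = 2.0),
                       quiet = TRUE),
               "bounds")
  expect_error(load_run_config(list(model = "nonsense")), "elastic")
})

test_that("a one-value sweep equals the plain run", {
  base <- tempfile()
  r <- cmd_run(bar_config(file.path(base, "single")), quiet = TRUE)
  sw <- cmd_sweep(bar_config(file.path(base, "sweep")), rho0_list = 0.8,
                  quiet = TRUE)
  expect_length(sw, 1)
  expect_equal(sw[["0.8"]]$density, r$density)
  expect_true(file.exists(file.path(base, "sweep", "sweep_traces.csv")))
})

test_that("perturbed initial densities give nearby but distinct fields", {
  base <- tempfile()
  cfg <- list(mesh = list(fixture = "femur2d", resolution = 0.5),
              schedule = list(dt = 0.2, t_remodel = 3),
              frames = numeric(0), output = base)
  sw <- cmd_sweep(cfg, rho0_list = c(0.76, 0.8, 0.84), quiet = TRUE)
  expect_length(sw, 3)
  traces <- utils::read.csv(file.path(base, "sweep_traces.csv"))
  expect_equal(ncol(traces), 4)
  d1 <- density_difference(sw[["0.76"]]$density, sw[["0.8"]]$density)
  expect_true(any(d1 != 0))
  expect_lt(mean(abs(d1)), 0.2)   # similar but not the same
  diffs <- utils::read.csv(file.path(base, "sweep_final_differences.csv"))
  expect_equal(nrow(diffs), 3)
})

test_that("opposite extreme starts converge to the analytic bar equilibrium", {
  base <- tempfile()
  cfg <- bar_config(base, schedule = list(dt = 0.2, t_remodel = 600),
                    frames = numeric(0))
  sw <- cmd_sweep(cfg, rho0_list = c(0.2, 1.4), quiet = TRUE)
  rho_star <- analytic_equilibrium_density(3, table1)
  for (run in sw)
    expect_lt(max(abs(run$density - rho_star)), 1e-3)
})

test_that("cmd_validate computes and writes the comparison metrics", {
  outdir <- tempfile()
  run <- cmd_run(bar_config(outdir), quiet = TRUE)
  ctr <- element_centroids(run$mesh)
  pts <- data.frame(x_mm = ctr[, 1], y_mm = ctr[, 2],
                    density_gcm3 = run$density)
  # self-comparison
  suppressMessages({
    m0 <- cmd_validate(run, pts)
    expect_equal(m0$rms, 0)
    expect_equal(m0$mean_deviation, 0)
    # constant offset: rms = mean deviation = 0.1
    pts$density_gcm3 <- run$density + 0.1
    out_json <- tempfile(fileext = ".json")
    m1 <- cmd_validate(run, pts, out = out_json)
    expect_equal(m1$rms, 0.1, tolerance = 1e-10)
    expect_equal(m1$mean_deviation, 0.1, tolerance = 1e-10)
    written <- jsonlite::read_json(out_json)
    expect_equal(written$rms_gcm3, 0.1, tolerance = 1e-10)
    # reference point outside the mesh
    bad <- rbind(pts, data.frame(x_mm = 999, y_mm = 999, density_gcm3 = 1))
    expect_error(cmd_validate(run, bad), "outside")
  })
  expect_error(cmd_validate(run, tempfile()), "not found")
})

test_that("YAML configs load with defaults resolved", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("model: piezo",
               "mesh:",
               "  fixture: femur2d",
               "  resolution: 0.5",
               "schedule:",
               "  dt: 0.5",
               "  t_remodel: 2",
               "seed: 42"), path)
  cfg <- load_run_config(path)
  expect_equal(cfg$model, "piezo")
  expect_equal(cfg$initial_density, 0.8)
  expect_equal(cfg$frames, c(0, 150, 300))
  expect_equal(cfg$seed, 42)
})
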