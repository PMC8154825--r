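# Time integration of the density field under the scheduled mechanical
# and electrical loading program.

#' Gait load cases
#'
#' The three load cases characterising the daily load history of walking:
#' a parabolic distributed load on the femoral head and the abductor
#' reaction on the greater trochanter, with angles measured from the
#' vertical.
#'
#' @return Data frame with columns `head_force` (N), `head_angle` (deg),
#'   `troch_force` (N), `troch_angle` (deg); one row per load case.
#' @export
default_load_cases <- function() {
  data.frame(head_force = c(2317, 1158, 1548),
             head_angle = c(24, -15, 56),
             troch_force = c(703, 351, 468),
             troch_angle = c(28, -8, 35))
}

#' Remodelling schedule
#'
#' The phase calendar of a simulation: a remodelling period under daily
#' gait loading (phase 1, days 0 to `t_remodel`), optionally followed by a
#' reduced-physical-activity period (phase 2, to `t_end`) in which the
#' mechanical loads are applied only once every `reduced_activity_every`
#' days while a therapeutic surface charge may act continuously.
#'
#' @param dt Time-step size (day).
#' @param t_remodel End of the remodelling period (day).
#' @param t_end End of the simulation (day); equal to `t_remodel` for a
#'   phase-1-only run.
#' @param reduced_activity_every Days between load applications in phase 2.
#' @param charge Stimulation surface charge density q_N (C/mm^2) applied to
#'   the trochanter during phase 2 when stimulation is enabled.
#' @param load_cases Data frame as [default_load_cases()].
#' @return Object of class `remodel_schedule`.
#' @export
remodel_schedule <- function(dt = 0.1, t_remodel = 300, t_end = t_remodel,
                             reduced_activity_every = 3, charge = 2e-9,
                             load_cases = default_load_cases()) {
  if (dt <= 0) stop("dt must be > 0")
  if (t_remodel > t_end) stop("t_remodel must be <= t_end")
  if (!nrow(load_cases)) stop("load_cases must be nonempty")
  if (reduced_activity_every < 1) stop("reduced_activity_every must be >= 1")
  structure(list(dt = dt, t_remodel = t_remodel, t_end = t_end,
                 reduced_activity_every = reduced_activity_every,
                 charge = charge, load_cases = load_cases),
            class = "remodel_schedule")
}

#' Density evolution rate
#'
#' The strain-adaptive remodelling law
#' \deqn{d\rho/dt = B (U/\rho - S_r)}
#' with the strain energy density U as mechanical stimulus: density grows
#' where the SED per unit density exceeds the reference stimulus and
#' resorbs where it falls short (disuse).
#'
#' @param U Strain energy density stimulus (MPa = J/cm^3), vectorised.
#' @param rho Apparent density (g/cm^3), > 0.
#' @param params A [material_params()].
#' @return Rate in g/(cm^3 day).
#' @examples
#' density_rate(0.0064, 0.8)  # 0.004
#' @export
density_rate <- function(U, rho, params = material_params()) {
  if (any(rho <= 0)) stop("density must be positive")
  params$B * (U / rho - params$S_r)
}

#' One forward-Euler density step with bound clamping
#'
#' \eqn{\rho_n = clamp(\rho_{n-1} + \Delta t\, d\rho/dt,\ \rho_a, \rho_b)}.
#'
#' @param rho Densities at the current step (g/cm^3).
#' @param rates Rates from [density_rate()].
#' @param dt Time-step size (day).
#' @param params A [material_params()].
#' @return Updated density vector, elementwise within
#'   `[rho_min, rho_max]`.
#' @export
step_density <- function(rho, rates, dt, params = material_params()) {
  pmin(pmax(rho + dt * rates, params$rho_min), params$rho_max)
}

#' Volume-weighted average density
#'
#' Area-times-thickness weighted mean of the femur density field over an
#' element mask.
#'
#' @param field Density per femur element (g/cm^3).
#' @param mesh A [bone_mesh()].
#' @param mask Optional logical mask, either over all elements or over the
#'   femur elements only; default all femur elements.
#' @return Average density (g/cm^3).
#' @export
average_density <- function(field, mesh, mask = NULL) {
  femur <- mesh$region == "FEMUR"
  if (length(field) != sum(femur))
    stop("field must have one density per femur element")
  w <- (abs(element_areas(mesh)) * element_thickness(mesh))[femur]
  if (is.null(mask)) mask <- rep(TRUE, sum(femur))
  if (length(mask) == length(femur)) mask <- mask[femur]
  if (length(mask) != sum(femur))
    stop("mask length matches neither the element nor the femur-element count")
  if (!any(mask)) stop("empty region-of-interest mask")
  sum(field[mask] * w[mask]) / sum(w[mask])
}

#' Elementwise density difference
#'
#' @param field_a,field_b Density fields on the same mesh.
#' @return `field_a - field_b`.
#' @export
density_difference <- function(field_a, field_b) {
  if (length(field_a) != length(field_b))
    stop("density fields have different lengths")
  field_a - field_b
}

# ---------------------------------------------------------------------------
# Fast per-step solver machinery: the constrained system pattern is fixed
# over a run, only the per-element density scale changes, so the sparse
# pattern, the Dirichlet reduction and the triplet->slot aggregation map
# are precomputed once.

model_triplets <- function(model) {
  n <- model$n
  ku <- model$kuu
  if (!model$piezo)
    return(list(i = ku$i, j = ku$j, v = ku$v, e = ku$e,
                type = rep(1L, length(ku$i)), ndof = 2L * n))
  ka <- model$kup
  kp <- model$kpp
  list(i = c(ku$i, ka$i, 2L * n + ka$j, 2L * n + kp$i),
       j = c(ku$j, 2L * n + ka$j, ka$i, 2L * n + kp$j),
       v = c(ku$v, ka$v, -ka$v, kp$v),
       e = c(ku$e, ka$e, ka$e, kp$e),
       type = c(rep(1L, length(ku$i)), rep(2L, 2L * length(ka$i)),
                rep(2L, length(kp$i))),
       ndof = 3L * n)
}

prepare_run_solver <- function(model, bcs) {
  tr <- model_triplets(model)
  fixed <- fixed_dofs(model, bcs)
  free <- setdiff(seq_len(tr$ndof), fixed$idx)
  map <- integer(tr$ndof)
  map[free] <- seq_along(free)
  keep <- map[tr$i] > 0L & map[tr$j] > 0L
  ri <- map[tr$i[keep]]; rj <- map[tr$j[keep]]
  v <- tr$v[keep]; el <- tr$e[keep]; ty <- tr$type[keep]
  nf <- length(free)
  slot_key <- (as.numeric(rj) - 1) * nf + ri
  ord <- order(slot_key)
  ri <- ri[ord]; rj <- rj[ord]; v <- v[ord]; el <- el[ord]; ty <- ty[ord]
  slot_key <- slot_key[ord]
  uk <- unique(slot_key)
  pos <- findInterval(slot_key, uk)
  row0 <- as.integer((uk - 1) %% nf)
  colidx <- as.integer((uk - 1) %/% nf) + 1L
  p <- c(0L, cumsum(tabulate(colidx, nbins = nf)))
  template <- methods::new("dgCMatrix", i = row0, p = as.integer(p),
                           x = numeric(length(uk)), Dim = c(nf, nf))
  list(model = model, free = free, nfree = nf, v = v, el = el, ty = ty,
       pos = pos, nslot = length(uk), template = template)
}

run_step_matrix <- function(rs, rho_femur) {
  s <- density_scales(rs$model, rho_femur)
  fac <- ifelse(rs$ty == 1L, s$sE[rs$el], s$sA[rs$el])
  x <- rowsum(rs$v * fac, rs$pos, reorder = TRUE)
  K <- rs$template
  K@x <- as.numeric(x)
  K
}

#' Mechanical stimulus of one day's loading program
#'
#' Solves one quasi-static problem per active load case and returns the
#' arithmetic mean of the per-element strain-energy-density fields over the
#' femur elements.  On no-load days with stimulation active, solves with
#' zero tractions and the surface charge alone; on no-load days without
#' stimulation the stimulus is zero (pure disuse).
#'
#' @param mesh A [bone_mesh()].
#' @param density Apparent density per femur element (g/cm^3).
#' @param params A [material_params()].
#' @param bcs A [boundary_conditions()].
#' @param load_cases Data frame as [default_load_cases()]; zero rows for a
#'   no-load day.
#' @param piezo Solve the coupled problem?
#' @param charge Surface charge density (C/mm^2) on `bcs$charge_segment`,
#'   or `NULL`/0 for none.
#' @param combiner `"mean"` (default, the time-average of a sequential
#'   within-day application under quasi-statics) or `"sum"`.
#' @return SED stimulus per femur element (MPa).
#' @export
daily_stimulus <- function(mesh, density, params = material_params(),
                           bcs = boundary_conditions(mesh),
                           load_cases = default_load_cases(),
                           piezo = FALSE, charge = NULL,
                           combiner = c("mean", "sum")) {
  combiner <- match.arg(combiner)
  model <- build_fem_model(mesh, params, piezo)
  rs <- prepare_run_solver(model, bcs)
  F <- run_case_loads(model, bcs, load_cases, if (piezo) charge else NULL)
  if (is.null(F)) return(numeric(sum(model$femur)))
  stim_step(rs, density, F, combiner)$stimulus
}

# Full-length RHS columns for the active load cases (or the charge-only
# column); NULL when nothing acts.
run_case_loads <- function(model, bcs, load_cases, charge) {
  ndof <- if (model$piezo) 3L * model$n else 2L * model$n
  qvec <- NULL
  if (model$piezo && !is.null(charge) && charge != 0)
    qvec <- surface_charge_vector(model$mesh, bcs$charge_segment, charge)
  cols <- list()
  if (!is.null(load_cases) && nrow(load_cases)) {
    for (r in seq_len(nrow(load_cases))) {
      f <- parabolic_traction_vector(model$mesh, bcs$head_segment,
                                     load_cases$head_force[r],
                                     load_cases$head_angle[r], "down") +
        parabolic_traction_vector(model$mesh, bcs$trochanter_segment,
                                  load_cases$troch_force[r],
                                  load_cases$troch_angle[r], "up")
      col <- numeric(ndof)
      col[seq_len(2L * model$n)] <- f
      if (!is.null(qvec)) col[2L * model$n + seq_len(model$n)] <- qvec
      cols[[r]] <- col
    }
  } else if (!is.null(qvec)) {
    col <- numeric(ndof)
    col[2L * model$n + seq_len(model$n)] <- qvec
    cols[[1]] <- col
  }
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

# One multi-RHS solve + SED combination.  Returns the femur stimulus and
# the first-column full solution for tracing/frames.
stim_step <- function(rs, rho, Ffull, combiner = "mean") {
  model <- rs$model
  K <- run_step_matrix(rs, rho)
  Ffree <- Ffull[rs$free, , drop = FALSE]
  X <- solve_equilibrated(K, Ffree)
  n <- model$n
  ncase <- ncol(X)
  sed <- matrix(0, model$ne, ncase)
  Ufull <- matrix(0, if (model$piezo) 3L * n else 2L * n, ncase)
  Ufull[rs$free, ] <- X
  phimat <- NULL
  for (cse in seq_len(ncase)) {
    u <- Ufull[seq_len(2L * n), cse]
    phi <- if (model$piezo) Ufull[2L * n + seq_len(n), cse] else NULL
    fl <- recover_fields(model, rho, u, phi)
    sed[, cse] <- fl$sed
  }
  if (model$piezo) phimat <- Ufull[2L * n + seq_len(n), , drop = FALSE]
  stim <- if (combiner == "mean") rowMeans(sed) else rowSums(sed)
  list(stimulus = stim[model$femur],
       u = matrix(Ufull[seq_len(2L * n), 1], ncol = 2, byrow = TRUE),
       phi = if (model$piezo) phimat[, 1] else NULL,
       min_phi = if (model$piezo) min(phimat) else NA_real_,
       max_phi = if (model$piezo) max(phimat) else NA_real_,
       sed_full = rowMeans(sed))
}

#' Run a strain-adaptive remodelling simulation
#'
#' Integrates the density field with the explicit Euler scheme under the
#' scheduled loading program.  Phase 1 (up to `t_remodel`) applies all gait
#' load cases every iteration; phase 2 applies them only every
#' `reduced_activity_every` days and, when `stimulation` is enabled on the
#' coupled model, applies the surface charge every iteration.  The run is
#' fully deterministic.
#'
#' @param mesh A [bone_mesh()].
#' @param params A [material_params()].
#' @param schedule A [remodel_schedule()].
#' @param rho0 Uniform initial density (scalar, g/cm^3) or a per-femur-
#'   element field.
#' @param model `"elastic"` or `"piezo"`.
#' @param stimulation Apply the therapeutic surface charge in phase 2?
#'   (requires `model = "piezo"`).
#' @param bcs A [boundary_conditions()].
#' @param frame_times Days at which to keep full result frames.
#' @param rois Named list of element masks for region-of-interest traces.
#' @param t_start Start day (nonzero to continue from a saved field).
#' @param combiner Load-case SED combination, see [daily_stimulus()].
#' @param load_vectors Optional list of raw mechanical load vectors (length
#'   `2 * n_nodes`) replacing the gait load cases; used by the benchmark
#'   fixtures (e.g. a uniform end traction on a bar).
#' @return Object of class `remodel_run`: `density` (final femur field),
#'   `trace` (data frame: step, day, average density, ROI averages, min
#'   potential), `frames` (list of [result_frame()]), plus the settings.
#' @export
run_simulation <- function(mesh, params = material_params(),
                           schedule = remodel_schedule(), rho0 = 0.8,
                           model = c("elastic", "piezo"),
                           stimulation = FALSE,
                           bcs = boundary_conditions(mesh),
                           frame_times = NULL, rois = NULL,
                           t_start = 0, combiner = "mean",
                           load_vectors = NULL) {
  model <- match.arg(model)
  piezo <- model == "piezo"
  if (stimulation && !piezo)
    stop("stimulation requires the piezoelectric model")
  femur <- mesh$region == "FEMUR"
  nf <- sum(femur)
  rho <- if (length(rho0) == 1L) rep(rho0, nf) else as.numeric(rho0)
  if (length(rho) != nf)
    stop("rho0 must be scalar or one value per femur element")
  check_density_bounds(rho, params, "initial density")

  fm <- build_fem_model(mesh, params, piezo)
  rs <- prepare_run_solver(fm, bcs)
  ndof <- if (piezo) 3L * fm$n else 2L * fm$n
  if (!is.null(load_vectors)) {
    F_loads <- vapply(load_vectors, function(f) {
      col <- numeric(ndof); col[seq_len(2L * fm$n)] <- f; col
    }, numeric(ndof))
    qvec <- if (piezo && stimulation && schedule$charge != 0)
      surface_charge_vector(mesh, bcs$charge_segment, schedule$charge) else NULL
    F_loads_charged <- if (!is.null(qvec))
      F_loads + rep(c(numeric(2L * fm$n), qvec), times = ncol(F_loads)) else NULL
    F_charge_only <- if (!is.null(qvec))
      matrix(c(numeric(2L * fm$n), qvec), ncol = 1) else NULL
  } else {
    F_loads <- run_case_loads(fm, bcs, schedule$load_cases, NULL)
    F_loads_charged <- if (piezo && stimulation)
      run_case_loads(fm, bcs, schedule$load_cases, schedule$charge) else NULL
    F_charge_only <- if (piezo && stimulation)
      run_case_loads(fm, bcs, NULL, schedule$charge) else NULL
  }

  dt <- schedule$dt
  nstep <- as.integer(round((schedule$t_end - t_start) / dt))
  if (nstep < 1L) stop("schedule spans no time steps")
  w_roi <- rois %||% list()

  day_v <- avg_v <- minphi_v <- maxphi_v <- numeric(nstep)
  roi_m <- matrix(0, nstep, length(w_roi),
                  dimnames = list(NULL, names(w_roi)))
  frames <- list()
  maybe_frame <- function(t, sol, rho_now) {
    if (is.null(frame_times)) return()
    hit <- any(abs(frame_times - t) < dt / 2)
    if (!hit) return()
    dens <- rep(NA_real_, nrow(mesh$elements))
    dens[femur] <- rho_now
    sedv <- rep(NA_real_, nrow(mesh$elements))
    disp <- matrix(0, nrow(mesh$nodes), 2)
    phi <- NULL
    if (!is.null(sol)) {
      sedv <- sol$sed_full
      sedv[!femur] <- NA_real_
      disp <- sol$u
      phi <- sol$phi
    }
    frames[[length(frames) + 1L]] <<-
      result_frame(t, disp, dens, sed = sedv, potential = phi)
  }

  sol <- NULL
  # frame at the start time (initial state)
  maybe_frame(t_start, NULL, rho)

  for (s in seq_len(nstep)) {
    t_now <- t_start + (s - 1L) * dt
    day <- floor(t_now + 1e-9)
    phase2 <- day >= schedule$t_remodel && schedule$t_end > schedule$t_remodel
    loads_on <- if (!phase2) TRUE else
      ((day - schedule$t_remodel) %% schedule$reduced_activity_every) == 0
    charge_on <- phase2 && piezo && stimulation && schedule$charge != 0

    Fmat <- if (loads_on && charge_on) F_loads_charged
            else if (loads_on) F_loads
            else if (charge_on) F_charge_only
            else NULL

    if (is.null(Fmat)) {
      U <- numeric(nf)          # pure disuse
      sol <- NULL
    } else {
      sol <- stim_step(rs, rho, Fmat, combiner)
      U <- sol$stimulus
    }
    rate <- density_rate(U, rho, params)
    rho_new <- step_density(rho, rate, dt, params)
    if (any(!is.finite(rho_new)))
      stop(sprintf("non-finite density at step %d (day %.2f)", s, t_now))
    rho <- rho_new
    t_next <- t_start + s * dt

    day_v[s] <- t_next
    avg_v[s] <- average_density(rho, mesh)
    minphi_v[s] <- if (is.null(sol)) NA_real_ else sol$min_phi
    maxphi_v[s] <- if (is.null(sol)) NA_real_ else sol$max_phi
    for (kk in seq_along(w_roi))
      roi_m[s, kk] <- average_density(rho, mesh, w_roi[[kk]])

    maybe_frame(t_next, sol, rho)
  }

  trace <- data.frame(step = seq_len(nstep), day = day_v,
                      avg_density = avg_v, min_phi = minphi_v,
                      max_phi = maxphi_v)
  if (length(w_roi)) {
    roi_df <- as.data.frame(roi_m)
    names(roi_df) <- paste0("roi_", names(w_roi))
    trace <- cbind(trace, roi_df)
  }
  structure(list(density = rho, trace = trace, frames = frames,
                 mesh = mesh, params = params, schedule = schedule,
                 model = model, stimulation = stimulation,
                 t_start = t_start, rho0 = rho0),
            class = "remodel_run")
}

#' @export
print.remodel_run <- function(x, ...) {
  cat("<remodel_run> ", x$model,
      if (x$stimulation) " + stimulation", ": days ", x$t_start, "-",
      x$schedule$t_end, " (dt = ", x$schedule$dt, ")\n", sep = "")
  cat(sprintf("  final average density %.4f g/cm^3 (range %.4f-%.4f)\n",
              average_density(x$density, x$mesh), min(x$density),
              max(x$density)))
  cat("  trace rows:", nrow(x$trace), "; frames:", length(x$frames), "\n")
  invisible(x)
}
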