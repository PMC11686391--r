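# End-to-end study runners with reproducible manifests.

#' Coarse geometry preset
#'
#' Reduced-resolution variant of [geometry_params()] for fast exploratory
#' runs and tests (about 4x fewer cells than the default).
#' @param ... overrides passed to [geometry_params()].
#' @export
coarse_geometry_params <- function(...) {
  args <- list(mesh_resolution = 1.5e-3, ivc_resolution = 3e-3,
               bulk_factor = 1.8, h_max = 0.035, growth = 1.8)
  override <- list(...)
  args[names(override)] <- override
  do.call(geometry_params, args)
}

# md5 digest of an arbitrary R object (serialised to a temp file)
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Reproducibility manifest for a study run
#'
#' @param config arbitrary configuration object (digested).
#' @param seed the RNG seed used.
#' @param stages named numeric vector of stage wall times (s).
#' @return list with the config digest, seed, package version, timestamp
#'   and stage times.
#' @export
run_manifest <- function(config, seed, stages) {
  list(config_digest = object_digest(config), seed = seed,
       package_version = as.character(utils::packageVersion("pfasim")),
       timestamp = format(Sys.time(), tz = "UTC"),
       stage_seconds = stages)
}

#' Run a lethal-threshold study end to end
#'
#' Builds the domain, places the catheter, computes fiber frames, solves
#' the stationary field per unique amplitude, generates (or consumes)
#' lesion-volume observations, inverts each into a LET by bisection, and
#' summarises per-dose medians with a power-law fit.
#'
#' @param params a [geometry_params()] (use [coarse_geometry_params()] for
#'   quick runs).
#' @param segment_id target segment.
#' @param doses data.frame with `amplitude` and `n_trains`.
#' @param observations optional LesionObservation data.frame; when `NULL`,
#'   observations are generated at `true_let` with [gen_lesion_observations()].
#' @param true_let,lesions_per_dose,sigma_log generator settings.
#' @param model a [conductivity_model()].
#' @param seed RNG seed.
#' @param quiet suppress progress output.
#' @return list: `observations`, `estimates`, `medians`, `power_fit` (NULL
#'   with a single train count), `solutions`, `mesh`, `manifest`.
#' @export
run_let_study <- function(params = coarse_geometry_params(), segment_id = 8,
                          doses = data.frame(amplitude = 1500,
                                             n_trains = c(1, 4, 8, 16)),
                          observations = NULL, true_let = 450,
                          lesions_per_dose = 12, sigma_log = 0.15,
                          model = conductivity_model(), seed = 1,
                          quiet = TRUE) {
  stages <- c()
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))
  t0 <- tic()
  mesh <- place_catheter(assign_segments(build_domain(params, segment_id)),
                         segment_id)
  frames <- suppressWarnings(fiber_frames(mesh))
  stages["geometry"] <- lap(t0)
  t0 <- tic()
  amps <- unique(doses$amplitude)
  sols_by_amp <- lapply(amps, function(a)
    solve_field(mesh, frames = frames,
                protocol = pulse_protocol(amplitude = a), model = model,
                quiet = quiet))
  names(sols_by_amp) <- as.character(amps)
  solutions <- lapply(seq_len(nrow(doses)), function(d)
    sols_by_amp[[as.character(doses$amplitude[d])]])
  stages["field"] <- lap(t0)
  t0 <- tic()
  if (is.null(observations))
    observations <- gen_lesion_observations(solutions, mesh, doses,
                                            true_let = true_let,
                                            lesions_per_dose = lesions_per_dose,
                                            sigma_log = sigma_log, seed = seed)
  if (is.null(observations) || nrow(observations) == 0) {
    warning("no lesions to analyse; returning empty report")
    return(list(observations = observations, estimates = NULL, medians = NULL,
                power_fit = NULL, mesh = mesh,
                manifest = run_manifest(list(params, doses), seed, stages)))
  }
  sol_for_row <- solutions[match(
    paste(observations$amplitude),
    paste(doses$amplitude))]
  est <- observations
  est$let_value <- NA_real_; est$achieved_volume <- NA_real_
  for (r in seq_len(nrow(est))) {
    e <- tryCatch(estimate_let(sol_for_row[[r]], mesh,
                               est$measured_volume[r]),
                  error = function(e) NULL)
    if (!is.null(e)) {
      est$let_value[r] <- e$let_value
      est$achieved_volume[r] <- e$achieved_volume
    }
  }
  est <- est[!is.na(est$let_value), , drop = FALSE]
  med <- group_medians(est)
  pf <- if (length(unique(med$n_trains)) >= 2)
    fit_let_power(med) else NULL
  stages["inversion"] <- lap(t0)
  list(observations = observations, estimates = est, medians = med,
       power_fit = pf, solutions = sols_by_amp, mesh = mesh, frames = frames,
       manifest = run_manifest(list(params = params, doses = doses,
                                    true_let = true_let), seed, stages))
}

#' Run a thermal-damage study end to end
#'
#' Field solve, analytic laminar flow, transient pulsed heating, damage
#' metrics and depth probes for one or more flow scenarios (the low-flow
#' scenario is the worst case).
#'
#' @param params a [geometry_params()].
#' @param segment_id target segment (default mid-posterior, the placement
#'   with the highest predicted current).
#' @param protocol a [pulse_protocol()].
#' @param scenarios character vector from `c("low", "high")`.
#' @param model a [conductivity_model()].
#' @param materials a [thermal_materials()].
#' @param probe_depths probe depths below the tip, m.
#' @param seed RNG seed (recorded in the manifest; the solver itself is
#'   deterministic).
#' @param quiet suppress progress output.
#' @return list: per-scenario `runs` (history, damage, probe maxima),
#'   `field`, `mesh`, `manifest`.
#' @export
run_thermal_study <- function(params = coarse_geometry_params(),
                              segment_id = 8,
                              protocol = pulse_protocol(),
                              scenarios = "low",
                              model = conductivity_model(),
                              materials = thermal_materials(),
                              probe_depths = c(1e-3, 3e-3, 7e-3),
                              seed = 1, quiet = TRUE) {
  stages <- c()
  t0 <- Sys.time()
  mesh <- place_catheter(assign_segments(build_domain(params, segment_id)),
                         segment_id)
  frames <- suppressWarnings(fiber_frames(mesh))
  stages["geometry"] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  t0 <- Sys.time()
  field <- solve_field(mesh, frames = frames, protocol = protocol,
                       model = model, quiet = quiet)
  stages["field"] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  sched <- build_schedule(protocol)
  runs <- list()
  for (sc in scenarios) {
    t0 <- Sys.time()
    flow <- build_velocity_field(mesh, flow_scenario(sc))
    hist <- solve_heat(mesh, field, flow, sched, materials = materials,
                       model = model, frames = frames, protocol = protocol,
                       probe_depths = probe_depths, quiet = quiet)
    dmg <- arrhenius_damage(hist, mesh)
    runs[[sc]] <- list(
      history = hist, damage = dmg,
      probe_max = probe_max_temperatures(hist),
      dose_volume_mm3 = dmg$dose_volume_mm3,
      arrhenius_volume_mm3 = dmg$arrhenius_volume_mm3,
      abl_interface_maxT = hist$abl_interface_maxT,
      ret_interface_maxT = hist$ret_interface_maxT)
    stages[paste0("thermal_", sc)] <-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  list(runs = runs, field = field, mesh = mesh, frames = frames,
       manifest = run_manifest(list(params = params, protocol = protocol,
                                    scenarios = scenarios), seed, stages))
}

#' Export a mesh and per-cell fields to legacy VTK
#'
#' Writes an ASCII `RECTILINEAR_GRID` file with CELL_DATA arrays (region
#' and segment labels plus any supplied numeric fields), viewable in
#' ParaView.
#'
#' @param mesh a tensor `pfa_mesh`.
#' @param file output path (`.vtk`).
#' @param cell_data named list of per-cell numeric vectors.
#' @return the file path, invisibly.
#' @export
write_vtk <- function(mesh, file, cell_data = list()) {
  stopifnot(mesh$type == "tensor")
  con <- file(file, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("pfasim export")
  wl("ASCII")
  wl("DATASET RECTILINEAR_GRID")
  wl(sprintf("DIMENSIONS %d %d %d", mesh$nx + 1L, mesh$ny + 1L, mesh$nz + 1L))
  wl(sprintf("X_COORDINATES %d double", mesh$nx + 1L))
  wl(paste(format(mesh$xs, digits = 9), collapse = " "))
  wl(sprintf("Y_COORDINATES %d double", mesh$ny + 1L))
  wl(paste(format(mesh$ys, digits = 9), collapse = " "))
  wl(sprintf("Z_COORDINATES %d double", mesh$nz + 1L))
  wl(paste(format(mesh$zs, digits = 9), collapse = " "))
  wl(sprintf("CELL_DATA %d", mesh$n_cells))
  arrays <- c(list(region = mesh$region), cell_data)
  if (!is.null(mesh$segment_id)) arrays$segment_id <- mesh$segment_id
  for (nm in names(arrays)) {
    wl(sprintf("SCALARS %s double 1", nm))
    wl("LOOKUP_TABLE default")
    writeLines(format(as.numeric(arrays[[nm]]), digits = 7), con)
  }
  invisible(file)
}
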