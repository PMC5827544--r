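# Simulated online dose-reconstruction loop at the 25 Hz machine-log rate:
# per tick, select the respiratory phase from the target position, fetch the
# tick's phase dose cube, map energy to the reference grid with the
# configured DVS layout, divide by the phase's precomputed transferred mass
# and add the increment to the accumulated dose.

#' Select the respiratory phase from a target position
#'
#' Nearest phase centroid by Euclidean distance; ties resolve to the lower
#' phase index.
#'
#' @param position length-3 target position (mm).
#' @param phase_centroids P x 3 matrix of per-phase target positions (mm),
#'   row `i + 1` for phase `i` (see [phase_centroids()]).
#' @return 0-based phase index.
#' @export
phase_from_position <- function(position, phase_centroids) {
  phase_centroids <- as.matrix(phase_centroids)
  if (nrow(phase_centroids) < 1L)
    stop("phase_from_position: empty centroid table")
  d2 <- rowSums(sweep(phase_centroids, 2, as.numeric(position), `-`)^2)
  which.min(d2) - 1L
}

#' Precompute per-phase DVS tables and transferred mass
#'
#' For each phase: HU image -> density -> per-image-voxel mass, compile the
#' displacement field into push records plus the requested layout, and cache
#' the transferred-mass volume on the reference grid. The cached mass is
#' validated for conservation (relative residual <= 1e-9). These are the
#' per-phase precomputations of the online workflow; only the energy mapping
#' and the division remain per tick.
#'
#' @param phases list of per-phase lists with elements `image` (HU
#'   [scalar_volume()]) and `dvf` ([displacement_field()]), e.g. from
#'   [generate_phase()].
#' @param alignment the image/dose [grid_alignment()]; the reference energy
#'   grid is the dose grid.
#' @param layout DVS layout used per tick: `"push"`, `"pull"` or
#'   `"unified"`.
#' @param n_slabs z-slab count for the pull/unified gathers.
#' @param precision `"double"` or `"single"` accumulation.
#' @param mask optional per-image-voxel region of interest.
#' @return list of `phase_bundle` objects.
#' @export
precompute_phase_bundles <- function(phases, alignment,
                                     layout = c("unified", "pull", "push"),
                                     n_slabs = 1L,
                                     precision = c("double", "single"),
                                     mask = NULL) {
  layout <- match.arg(layout)
  precision <- match.arg(precision)
  stopifnot(inherits(alignment, "grid_alignment"))
  ref_grid <- alignment$dose_grid
  lapply(phases, function(ph) {
    mass <- image_voxel_mass(hu_to_density(ph$image))
    push <- compile_push(ph$dvf, ref_grid, mask = mask)
    table <- switch(layout,
                    push = push,
                    pull = compile_pull(push, ref_grid),
                    unified = compile_unified(push, ref_grid))
    mass_ref <- map_mass(mass, table, ref_grid, n_slabs = n_slabs,
                         precision = precision)
    res <- attr(mass_ref, "conservation_residual")
    if (res > 1e-9)
      stop(sprintf("precompute_phase_bundles: mass conservation residual %.3g > 1e-9", res))
    structure(list(table = table, push = push, mass_image = mass,
                   mass_ref = mass_ref,
                   n_used = sum(push$is_used != 0L),
                   n_excluded = sum(push$is_used == 0L)),
              class = "phase_bundle")
  })
}

#' Configuration of a reconstruction run
#'
#' Bundles everything [run_reconstruction()] needs. `dose_provider` is a
#' function `(phase, tick) -> dose scalar_volume` standing in for the
#' dose-influence-matrix stage of the online workflow; for the phantom use
#' `function(phase, tick) generate_tick_dose(spec, phase, tick)`.
#'
#' @param bundles list of phase bundles from [precompute_phase_bundles()].
#' @param alignment the image/dose [grid_alignment()].
#' @param trace a [breathing_trace()] driving phase selection.
#' @param centroids P x 3 matrix of phase centroids.
#' @param dose_provider function `(phase, tick)` returning the tick's dose
#'   cube on the dose grid.
#' @param method `"emt"` or `"ddm"`.
#' @param layout DVS layout for the per-tick energy mapping (must match the
#'   bundles).
#' @param precision `"double"` or `"single"`.
#' @param n_slabs z-slab count for pull/unified.
#' @param mass_floor minimum transferred mass (g) below which accumulated
#'   dose is 0.
#' @param output_dir optional directory; if set, the accumulated dose
#'   (NIfTI), run log (JSON), per-tick metrics (CSV) and resolved settings
#'   (YAML) are written there.
#' @return an object of class `reconstruction_config`.
#' @export
reconstruction_config <- function(bundles, alignment, trace, centroids,
                                  dose_provider,
                                  method = c("emt", "ddm"),
                                  layout = c("unified", "pull", "push"),
                                  precision = c("double", "single"),
                                  n_slabs = 1L, mass_floor = 1e-6,
                                  output_dir = NULL) {
  method <- match.arg(method)
  layout <- match.arg(layout)
  precision <- match.arg(precision)
  stopifnot(inherits(trace, "breathing_trace"),
            inherits(alignment, "grid_alignment"),
            is.function(dose_provider), length(bundles) >= 1L)
  structure(list(bundles = bundles, alignment = alignment, trace = trace,
                 centroids = as.matrix(centroids),
                 dose_provider = dose_provider, method = method,
                 layout = layout, precision = precision,
                 n_slabs = as.integer(n_slabs), mass_floor = mass_floor,
                 output_dir = output_dir),
            class = "reconstruction_config")
}

map_energy_layout <- function(dose, bundle, config, ref_grid) {
  switch(config$layout,
         push = map_energy_push(dose, bundle$mass_image, bundle$table,
                                config$alignment, ref_grid,
                                precision = config$precision),
         pull = map_energy_pull(dose, bundle$mass_image, bundle$table,
                                config$alignment, ref_grid,
                                n_slabs = config$n_slabs,
                                precision = config$precision),
         unified = map_energy_unified(dose, bundle$mass_image, bundle$table,
                                      config$alignment, ref_grid,
                                      n_slabs = config$n_slabs,
                                      precision = config$precision))
}

#' Run the online reconstruction loop
#'
#' For every trace tick: (1) select the respiratory phase from the target
#' position, (2) obtain that tick's phase dose cube, (3) map energy to the
#' reference grid with the configured layout, (4) divide by the phase's
#' cached transferred mass and add the per-tick dose increment to the
#' accumulated volume. With `method = "ddm"` the per-tick increment is the
#' direct-dose-mapping baseline instead. Per-tick wall-clock latency,
#' conservation residuals, scatter-operation counts and floored-voxel counts
#' are logged (informational; latency is hardware-bound and never asserted).
#'
#' @param config a [reconstruction_config()].
#' @return an object of class `emt_reconstruction`: accumulated dose volume,
#'   tick count and the per-tick log.
#' @export
run_reconstruction <- function(config) {
  stopifnot(inherits(config, "reconstruction_config"))
  ref_grid <- config$alignment$dose_grid
  acc <- numeric(n_voxels(ref_grid))
  pos <- trace_positions(config$trace)
  n_ticks <- nrow(pos)
  log <- data.frame(tick = seq_len(n_ticks) - 1L,
                    time_s = config$trace$time_s,
                    phase = NA_integer_, n_records = NA_real_,
                    latency_s = NA_real_, conservation_residual = NA_real_,
                    floored_voxels = NA_real_)
  dose_cache <- list()
  for (k in seq_len(n_ticks)) {
    t0 <- proc.time()[["elapsed"]]
    phase <- phase_from_position(pos[k, ], config$centroids)
    if (phase + 1L > length(config$bundles))
      stop(sprintf("run_reconstruction: no bundle for phase %d", phase))
    bundle <- config$bundles[[phase + 1L]]
    key <- as.character(phase)
    dose <- dose_cache[[key]]
    if (is.null(dose)) {
      dose <- config$dose_provider(phase, k - 1L)
      dose_cache[[key]] <- dose
    }
    if (config$method == "emt") {
      energy <- map_energy_layout(dose, bundle, config, ref_grid)
      d_tick <- divide_energy_by_mass(energy, bundle$mass_ref,
                                      mass_floor = config$mass_floor)
      log$conservation_residual[k] <- attr(energy, "conservation_residual")
      log$floored_voxels[k] <- attr(d_tick, "floored_voxels")
    } else {
      d_tick <- ddm_map(dose, bundle$push, config$alignment, ref_grid)
    }
    acc <- acc + d_tick$values
    log$phase[k] <- phase
    log$n_records[k] <- bundle$n_used
    log$latency_s[k] <- proc.time()[["elapsed"]] - t0
  }
  state <- structure(list(dose = scalar_volume(ref_grid, acc, role = "dose"),
                          n_ticks = n_ticks, log = log,
                          method = config$method, layout = config$layout,
                          n_excluded = vapply(config$bundles,
                                              function(b) b$n_excluded, 0)),
                     class = "emt_reconstruction")
  if (!is.null(config$output_dir)) write_reconstruction(state, config)
  state
}

write_reconstruction <- function(state, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(state$dose, file.path(config$output_dir, "accumulated_dose.nii.gz"))
  utils::write.csv(state$log, file.path(config$output_dir, "ticks.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    method = state$method, layout = state$layout, n_ticks = state$n_ticks,
    mass_floor = config$mass_floor, n_slabs = config$n_slabs,
    precision = config$precision,
    total_floored = sum(state$log$floored_voxels, na.rm = TRUE),
    excluded_records_per_phase = as.numeric(state$n_excluded),
    max_conservation_residual = suppressWarnings(
      max(state$log$conservation_residual, na.rm = TRUE))
  ), file.path(config$output_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(list(method = state$method, layout = state$layout,
                        precision = config$precision,
                        n_slabs = config$n_slabs,
                        mass_floor = config$mass_floor,
                        n_phases = length(config$bundles)),
                   file.path(config$output_dir, "resolved_config.yaml"))
  invisible(state)
}

#' @export
print.emt_reconstruction <- function(x, ...) {
  cat(sprintf("emt_reconstruction (%s, %s layout): %d ticks\n",
              x$method, x$layout, x$n_ticks))
  cat(sprintf("  accumulated dose in [%g, %g] Gy; median tick latency %.1f ms\n",
              min(x$dose$values), max(x$dose$values),
              stats::median(x$log$latency_s) * 1000))
  invisible(x)
}

#' Summarize an accumulated-dose state
#'
#' Minimum / mean / maximum accumulated dose inside an optional region of
#' interest, plus the floored-voxel and excluded-record totals.
#'
#' @param state an `emt_reconstruction` from [run_reconstruction()].
#' @param roi_mask optional logical/0-1 vector or array on the reference
#'   grid; must select at least one voxel.
#' @return a one-row data.frame.
#' @export
summarize_reconstruction <- function(state, roi_mask = NULL) {
  stopifnot(inherits(state, "emt_reconstruction"))
  v <- state$dose$values
  if (!is.null(roi_mask)) {
    roi_mask <- as.logical(roi_mask)
    if (length(roi_mask) != length(v))
      stop("summarize_reconstruction: ROI shape mismatch")
    if (!any(roi_mask)) stop("summarize_reconstruction: empty ROI")
    v <- v[roi_mask]
  }
  data.frame(min_gy = min(v), mean_gy = mean(v), max_gy = max(v),
             n_ticks = state$n_ticks,
             floored_voxels = sum(state$log$floored_voxels, na.rm = TRUE),
             excluded_records = sum(state$n_excluded))
}

#' @export
summary.emt_reconstruction <- function(object, roi_mask = NULL, ...) {
  summarize_reconstruction(object, roi_mask)
}
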