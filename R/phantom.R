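# Seeded synthetic 4D phantom: lung-like reference anatomy, analytic
# superior-inferior respiratory deformation with per-phase scaling, matching
# displacement fields, Gaussian tracked-beam dose cubes and an elliptical
# target trace. Everything is deterministic given the spec's seed, so the
# full pipeline is testable without external data.

#' Specification of the synthetic 4D phantom
#'
#' Defaults mirror a phase-binned 4D lung planning set at reduced grid size:
#' image voxels 1 x 1 x 2 mm (the clinical relation of 2 x 2 x 1 image
#' voxels per 2 x 2 x 2 mm dose voxel), 10 respiratory phases, sinusoidal
#' superior-inferior compression of 8 mm peak amplitude (a typical lung
#' tumour excursion) and an elliptical target trajectory sampled at the
#' 40 ms (25 Hz) machine-log tick. The 64 x 64 x 40 image grid keeps the
#' full loop in the seconds range; clinical sizes (512 x 512 x 173) remain
#' reachable through the arguments.
#'
#' @param image_shape image grid voxel counts (default `c(64, 64, 40)`).
#' @param image_spacing image voxel size, mm (default `c(1, 1, 2)`).
#' @param dose_ratio integer image voxels per dose voxel per axis
#'   (default `c(2, 2, 1)`, i.e. 2 x 2 x 2 mm dose voxels).
#' @param n_phases number of respiratory phases P (>= 2, default 10).
#' @param amplitude_mm peak superior-inferior deformation amplitude (mm).
#' @param trajectory_semiaxes_mm ellipse semi-axes of the target trajectory
#'   (mm); the default z semi-axis equals `amplitude_mm` so the trace follows
#'   the deformed tumour centre.
#' @param beam_sigma_mm isotropic Gaussian beam sigma (mm).
#' @param dose_per_tick_gy peak dose delivered per 40 ms tick (Gy).
#' @param breathing_period_s breathing cycle length (s).
#' @param tick_s trace sampling interval (s, default 0.040).
#' @param hu_lung,hu_tissue HU of the lung and soft-tissue compartments.
#' @param noise_sd_hu standard deviation of the seeded HU noise.
#' @param seed integer seed determining all phantom outputs.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(64L, 64L, 40L),
                         image_spacing = c(1, 1, 2),
                         dose_ratio = c(2L, 2L, 1L),
                         n_phases = 10L,
                         amplitude_mm = 8,
                         trajectory_semiaxes_mm = c(2, 1, amplitude_mm),
                         beam_sigma_mm = 6,
                         dose_per_tick_gy = 0.01,
                         breathing_period_s = 4,
                         tick_s = 0.040,
                         hu_lung = -700,
                         hu_tissue = 0,
                         noise_sd_hu = 15,
                         seed = 1L) {
  image_shape <- as.integer(image_shape)
  dose_ratio <- as.integer(dose_ratio)
  if (n_phases < 2L) stop("phantom_spec: need at least 2 phases")
  if (any(image_shape %% dose_ratio != 0L))
    stop("phantom_spec: image shape must be divisible by the dose ratio")
  image_grid <- grid3d(origin = c(0, 0, 0), spacing = image_spacing,
                       shape = image_shape)
  dose_grid <- grid3d(origin = (dose_ratio - 1) / 2 * image_spacing,
                      spacing = image_spacing * dose_ratio,
                      shape = image_shape %/% dose_ratio)
  extent <- image_shape * image_spacing
  if (amplitude_mm <= 0 || amplitude_mm >= extent[3] / 4)
    stop("phantom_spec: amplitude must be positive and below a quarter of the z extent")
  spec <- structure(list(
    image_grid = image_grid, dose_grid = dose_grid,
    n_phases = as.integer(n_phases),
    amplitude_mm = amplitude_mm,
    trajectory_semiaxes_mm = as.numeric(trajectory_semiaxes_mm),
    beam_sigma_mm = beam_sigma_mm,
    dose_per_tick_gy = dose_per_tick_gy,
    breathing_period_s = breathing_period_s,
    tick_s = tick_s,
    hu_lung = hu_lung, hu_tissue = hu_tissue, noise_sd_hu = noise_sd_hu,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  geom <- phantom_geometry(spec)
  if (any(abs(geom$tumour_centre - geom$lung_centre) + geom$tumour_radius >
          geom$lung_semi))
    stop("phantom_spec: degenerate geometry (tumour not inside the lung)")
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %d phases, amplitude %g mm, seed %d\n",
              x$n_phases, x$amplitude_mm, x$seed))
  cat("  image "); print(x$image_grid)
  cat("  dose  "); print(x$dose_grid)
  invisible(x)
}

phantom_geometry <- function(spec) {
  g <- spec$image_grid
  extent <- g$shape * g$spacing
  centre <- g$origin + (g$shape - 1) / 2 * g$spacing
  list(centre = centre,
       lung_centre = centre,
       lung_semi = 0.35 * extent,
       tumour_centre = centre + c(0.06 * extent[1], 0, 0),
       tumour_radius = 0.10 * min(extent))
}

# run code under the spec's seed without disturbing the caller's RNG state
with_phantom_seed <- function(spec, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed + offset)
  force(code)
}

#' Generate the reference anatomy
#'
#' A lung-like HU pattern: soft tissue (~0 HU) containing a low-density
#' ellipsoidal lung (~-700 HU) with a spherical soft-tissue-density tumour,
#' plus seeded Gaussian HU noise. Deterministic given the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return HU [scalar_volume()] on the image grid.
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$image_grid
  geom <- phantom_geometry(spec)
  ijk <- ijk_index(g, seq_len(n_voxels(g)) - 1)
  pos <- voxel_centre(g, ijk)
  rel <- sweep(pos, 2, geom$lung_centre, `-`)
  in_lung <- rowSums(sweep(rel, 2, geom$lung_semi, `/`)^2) <= 1
  rt <- sweep(pos, 2, geom$tumour_centre, `-`)
  in_tum <- rowSums(rt^2) <= geom$tumour_radius^2
  hu <- rep(spec$hu_tissue, n_voxels(g))
  hu[in_lung] <- spec$hu_lung
  hu[in_tum] <- spec$hu_tissue
  noise <- with_phantom_seed(spec, 0L, stats::rnorm(n_voxels(g), 0, spec$noise_sd_hu))
  scalar_volume(g, hu + noise, role = "hu")
}

# s_i scaling of the deformation for phase i (0-based); phase 0 is the
# reference (s = 0).
phase_scale <- function(spec, i) sin(2 * pi * i / spec$n_phases)

# z-profile of the deformation: zero at both z faces, peak mid-volume
z_profile <- function(spec, z) {
  g <- spec$image_grid
  z0 <- g$origin[3] - g$spacing[3] / 2
  L <- g$shape[3] * g$spacing[3]
  sin(pi * (z - z0) / L)
}

# invert z' = z + A s sin(pi (z - z0)/L) by fixed-point iteration
invert_z <- function(spec, s, z_moving, tol_voxel = 1e-3, max_iter = 200L) {
  a <- spec$amplitude_mm * s
  tol <- tol_voxel * spec$image_grid$spacing[3]
  z <- z_moving
  for (iter in seq_len(max_iter)) {
    z_new <- z_moving - a * z_profile(spec, z)
    if (max(abs(z_new - z)) < tol) return(z_new)
    z <- z_new
  }
  stop("invert_z: fixed-point inversion did not converge (amplitude too large?)")
}

#' Generate one respiratory phase
#'
#' The analytic forward deformation moves reference point `x` in the
#' superior-inferior direction by `A * s_i * sin(pi z / L)` with per-phase
#' scale `s_i = sin(2 pi i / P)` (phase 0 is the reference, `s = 0`). The
#' phase image resamples the reference through the numerically inverted map
#' (fixed-point iteration to 1e-3 voxel), and the returned displacement
#' field maps moving-phase voxel centres to reference space -- the forward
#' direction consumed by [compile_push()].
#'
#' @param spec a [phantom_spec()].
#' @param i 0-based phase index in `0:(n_phases - 1)`.
#' @param reference optional precomputed [generate_reference()] volume.
#' @return list with `image` (HU [scalar_volume()]) and `dvf`
#'   ([displacement_field()]).
#' @export
generate_phase <- function(spec, i, reference = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (i < 0 || i >= spec$n_phases) stop("generate_phase: phase index out of range")
  if (is.null(reference)) reference <- generate_reference(spec)
  g <- spec$image_grid
  s <- phase_scale(spec, i)
  z_slices <- g$origin[3] + (seq_len(g$shape[3]) - 1) * g$spacing[3]
  z_ref <- invert_z(spec, s, z_slices)

  # displacement of each moving voxel centre back to reference space (z only)
  dz <- z_ref - z_slices
  n <- n_voxels(g)
  per_slice <- g$shape[1] * g$shape[2]
  vectors <- cbind(numeric(n), numeric(n), rep(dz, each = per_slice))
  dvf <- displacement_field(g, vectors)

  # resample the reference along z at the inverted positions (linear)
  ref_arr <- as_array(reference)
  t_idx <- (z_ref - g$origin[3]) / g$spacing[3]
  t_idx <- pmin(pmax(t_idx, 0), g$shape[3] - 1)
  k0 <- pmin(floor(t_idx), g$shape[3] - 2)
  frac <- t_idx - k0
  img <- array(0, dim = g$shape)
  for (k in seq_len(g$shape[3])) {
    lo <- ref_arr[, , k0[k] + 1]
    hi <- ref_arr[, , k0[k] + 2]
    img[, , k] <- (1 - frac[k]) * lo + frac[k] * hi
  }
  list(image = scalar_volume(g, img, role = "hu"), dvf = dvf)
}

#' Per-phase target positions
#'
#' Centre-of-target positions of the P phases on the elliptical trajectory,
#' at phase angles `2 pi i / P`; used both by the trace generator and for
#' nearest-centroid phase selection.
#'
#' @param spec a [phantom_spec()].
#' @return P x 3 matrix of positions (mm), row `i + 1` for phase `i`.
#' @export
phase_centroids <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  theta <- 2 * pi * (seq_len(spec$n_phases) - 1) / spec$n_phases
  ellipse_position(spec, theta)
}

ellipse_position <- function(spec, theta) {
  geom <- phantom_geometry(spec)
  ax <- spec$trajectory_semiaxes_mm
  cbind(geom$tumour_centre[1] + ax[1] * cos(theta),
        geom$tumour_centre[2] + ax[2] * sin(theta),
        geom$tumour_centre[3] + ax[3] * sin(theta))
}

#' Generate the dose cube delivered in one tick
#'
#' An isotropic 3D Gaussian beam of peak `dose_per_tick_gy`, centred on the
#' phase-`i` target position (the beam tracks the target), evaluated on the
#' coarse dose grid. Deterministic; the tick argument is part of the
#' interface for time-varying delivery but the tracked beam does not depend
#' on it.
#'
#' @param spec a [phantom_spec()].
#' @param i 0-based phase index.
#' @param t tick index (unused by the tracked Gaussian beam).
#' @return dose [scalar_volume()] on the dose grid (Gy).
#' @export
generate_tick_dose <- function(spec, i, t = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (i < 0 || i >= spec$n_phases) stop("generate_tick_dose: phase index out of range")
  g <- spec$dose_grid
  centre <- phase_centroids(spec)[i + 1, ]
  ijk <- ijk_index(g, seq_len(n_voxels(g)) - 1)
  pos <- voxel_centre(g, ijk)
  r2 <- rowSums(sweep(pos, 2, centre, `-`)^2)
  dose <- spec$dose_per_tick_gy * exp(-r2 / (2 * spec$beam_sigma_mm^2))
  scalar_volume(g, dose, role = "dose")
}

#' Generate the target-position trace
#'
#' Samples the elliptical target trajectory every `tick_s` seconds (40 ms,
#' 25 Hz) for `duration` seconds; one breathing cycle per
#' `breathing_period_s`.
#'
#' @param spec a [phantom_spec()].
#' @param duration trace length in seconds (> 0).
#' @return a [breathing_trace()] with `floor(duration / tick_s) + 1` samples.
#' @export
generate_trace <- function(spec, duration) {
  stopifnot(inherits(spec, "phantom_spec"), duration > 0)
  t <- seq(0, by = spec$tick_s, length.out = floor(duration / spec$tick_s) + 1)
  theta <- 2 * pi * t / spec$breathing_period_s
  breathing_trace(t, ellipse_position(spec, theta))
}

#' Write a complete phantom data set to disk
#'
#' Writes the reference and per-phase HU images, the three displacement-field
#' components per phase (scalar NIfTI volumes, mm) and the breathing trace
#' CSV, as consumed by the command-line workflow.
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory (created if missing).
#' @param duration_s trace duration (default one breathing cycle).
#' @return the directory, invisibly.
#' @export
write_phantom <- function(spec, dir, duration_s = spec$breathing_period_s) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference(spec)
  write_volume(ref, file.path(dir, "reference.nii.gz"))
  for (i in seq_len(spec$n_phases) - 1L) {
    ph <- generate_phase(spec, i, reference = ref)
    write_volume(ph$image, file.path(dir, sprintf("phase_%02d.nii.gz", i)))
    write_volume(generate_tick_dose(spec, i),
                 file.path(dir, sprintf("dose_%02d.nii.gz", i)))
    for (a in 1:3) {
      comp <- RNifti::asNifti(array(ph$dvf$vectors[, a], dim = spec$image_grid$shape))
      RNifti::pixdim(comp) <- spec$image_grid$spacing
      aff <- rbind(cbind(diag(spec$image_grid$spacing), spec$image_grid$origin),
                   c(0, 0, 0, 1))
      comp <- RNifti::`qform<-`(comp, structure(aff, code = 2L))
      RNifti::writeNifti(comp, file.path(dir, sprintf("dvf_%02d_%s.nii.gz",
                                                      i, c("x", "y", "z")[a])),
                         datatype = "double")
    }
  }
  write_trace(generate_trace(spec, duration_s), file.path(dir, "trace.csv"))
  invisible(dir)
}
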