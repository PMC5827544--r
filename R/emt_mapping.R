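# Energy/mass transfer mapping: overlap weights, the scatter/gather kernels
# in the three DVS layouts, energy-by-mass division and the direct-dose
# mapping (DDM) baseline.

#' Trilinear overlap weights of a displaced virtual voxel
#'
#' A unit virtual voxel centred at offset `dxbar` (relative voxel
#' coordinates) from the nearest reference voxel centre overlaps up to 8
#' reference voxels; each weight is the shared volume fraction, so the
#' weights always sum to 1. Voxels are returned in the fixed traversal
#' pattern used by all kernels: base (minimum-index overlap corner), +x, +y,
#' +xy, +z, +xz, +yz, +xyz.
#'
#' @param dxbar length-3 offset in `(-0.5, 0.5]` per axis.
#' @param nearest_voxel 0-based ijk of the nearest reference voxel
#'   (default `c(0,0,0)`).
#' @param grid optional reference [grid3d()]; if given, flat indices are
#'   attached and bounds are checked.
#' @return list with `voxels` (8 x 3 ijk), `weights` (length 8, summing to
#'   1), and `flat` (8 flat indices) when `grid` is supplied.
#' @examples
#' w <- overlap_weights(c(0.25, 0.4, 0))
#' sum(w$weights)  # 1
#' @export
overlap_weights <- function(dxbar, nearest_voxel = c(0L, 0L, 0L), grid = NULL) {
  dxbar <- as.numeric(dxbar)
  if (length(dxbar) != 3L || any(!is.finite(dxbar)) ||
      any(dxbar <= -0.5) || any(dxbar > 0.5))
    stop("overlap_weights: offsets must lie in (-0.5, 0.5] per axis")
  uf <- unified_weight_factors(dxbar)
  base <- as.integer(nearest_voxel) + uf$base_offset
  steps <- as.matrix(expand.grid(o1 = 0:1, o2 = 0:1, o3 = 0:1))
  voxels <- sweep(steps, 2, base, `+`)
  dimnames(voxels) <- NULL
  w <- apply(steps, 1, function(o) {
    f <- ifelse(o == 1, 1 - uf$w0, uf$w0)
    (f[1] * f[2]) * f[3]
  })
  out <- list(voxels = voxels, weights = as.numeric(w))
  if (!is.null(grid)) out$flat <- flat_index(grid, voxels)
  out
}

#' Axis-aligned box-intersection oracle for overlap weights
#'
#' Independent geometric reference used in tests: for each neighbour at
#' integer offset `(-1, 0, 1)^3` of the nearest voxel it computes the volume
#' of intersection between the unit virtual voxel `[dx - 0.5, dx + 0.5]` and
#' that neighbour's unit cell, by explicit per-axis interval overlap. Shares
#' no code with [overlap_weights()].
#'
#' @param dxbar length-3 offset (any finite values; weights outside the
#'   overlap ensemble are 0).
#' @return list with `offsets` (27 x 3, integer steps from the nearest
#'   voxel) and `weights` (length 27).
#' @export
box_intersection_oracle <- function(dxbar) {
  dxbar <- as.numeric(dxbar)
  stopifnot(length(dxbar) == 3L, all(is.finite(dxbar)))
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dimnames(offsets) <- NULL
  axis_overlap <- function(dx, delta) {
    lo <- max(dx - 0.5, delta - 0.5)
    hi <- min(dx + 0.5, delta + 0.5)
    max(0, hi - lo)
  }
  w <- apply(offsets, 1, function(d) {
    axis_overlap(dxbar[1], d[1]) * axis_overlap(dxbar[2], d[2]) *
      axis_overlap(dxbar[3], d[3])
  })
  list(offsets = offsets, weights = as.numeric(w))
}

check_mapping_inputs <- function(dose_moving, mass_image, table, alignment,
                                 ref_grid) {
  stopifnot(inherits(table, "dvs_table"), inherits(ref_grid, "grid3d"),
            inherits(alignment, "grid_alignment"))
  if (!is.null(dose_moving)) {
    stopifnot(inherits(dose_moving, "scalar_volume"))
    if (!grids_equal(dose_moving$grid, alignment$dose_grid))
      stop("dose volume is not on the alignment's dose grid")
  }
  if (!is.null(mass_image)) {
    stopifnot(inherits(mass_image, "scalar_volume"))
    if (mass_image$role != "mass")
      stop("mass_image must have role 'mass' (see image_voxel_mass)")
    if (!grids_equal(mass_image$grid, alignment$image_grid))
      stop("mass volume is not on the alignment's image grid")
  }
  if (!all(table$image_shape == alignment$image_grid$shape))
    stop("DVS table was compiled for a different image grid")
  if (!all(table$ref_shape == ref_grid$shape))
    stop("DVS table was compiled for a different reference grid")
}

# Per-image-voxel transferred energy E_T = d(containing dose voxel) * m,
# in Gy g: dose is sampled piecewise-constant from the coarse dose grid.
transfer_energy <- function(dose_moving, mass_image, alignment) {
  d_img <- dose_moving$values[image_to_dose_map(alignment) + 1]
  d_img * mass_image$values
}

finish_energy <- function(values, ref_grid, total_in, role) {
  out <- scalar_volume(ref_grid, values, role = role)
  attr(out, "total_in") <- total_in
  attr(out, "conservation_residual") <-
    if (total_in > 0) abs(sum(values) - total_in) / total_in else 0
  out
}

#' Map phase energy to the reference grid (push layout)
#'
#' Serial scatter: records are processed in ascending image-voxel order; each
#' used record transfers `E_T = d * m` (phase dose at the image voxel's
#' containing dose voxel times the image-voxel mass) to its 8 overlap voxels
#' with trilinear weights. Total scattered energy equals the sum of used
#' `E_T` exactly (no clipping: out-of-bounds ensembles were excluded at
#' compile time). The result carries attributes `total_in` and
#' `conservation_residual`.
#'
#' @param dose_moving phase dose [scalar_volume()] on the coarse dose grid (Gy).
#' @param mass_image per-image-voxel mass [scalar_volume()] (g), from
#'   [image_voxel_mass()].
#' @param push_records a `dvs_push` table compiled against `ref_grid`.
#' @param alignment the image/dose [grid_alignment()].
#' @param ref_grid the reference energy [grid3d()].
#' @param precision `"double"` (default) or `"single"`; single-precision
#'   accumulation exists to study the reordering error of a float
#'   implementation.
#' @return energy [scalar_volume()] on `ref_grid` (Gy g).
#' @export
map_energy_push <- function(dose_moving, mass_image, push_records, alignment,
                            ref_grid, precision = c("double", "single")) {
  precision <- match.arg(precision)
  stopifnot(inherits(push_records, "dvs_push"))
  check_mapping_inputs(dose_moving, mass_image, push_records, alignment, ref_grid)
  et <- transfer_energy(dose_moving, mass_image, alignment)
  vals <- map_push_cpp(push_records$target_index, push_records$dXb,
                       push_records$is_used, et, ref_grid$shape,
                       precision == "single")
  finish_energy(vals, ref_grid, sum(et[push_records$is_used != 0L]), "energy")
}

#' Map phase energy to the reference grid (pull layout)
#'
#' Gather formulation of the same transfer: reference voxels are processed in
#' ascending order (decomposed into `n_slabs` contiguous z-slabs) and each
#' voxel gathers the contributions of records keyed to its neighbourhood.
#' Every reference voxel is computed by exactly one worker, so the gather is
#' race-free and the result is bitwise independent of `n_slabs`; it agrees
#' with [map_energy_push()] up to summation reordering.
#'
#' @inheritParams map_energy_push
#' @param pull_table a `dvs_pull` table from [compile_pull()].
#' @param n_slabs number of z-slabs (1 to the reference z-extent).
#' @return energy [scalar_volume()] on `ref_grid` (Gy g).
#' @export
map_energy_pull <- function(dose_moving, mass_image, pull_table, alignment,
                            ref_grid, n_slabs = 1L,
                            precision = c("double", "single")) {
  precision <- match.arg(precision)
  stopifnot(inherits(pull_table, "dvs_pull"))
  check_mapping_inputs(dose_moving, mass_image, pull_table, alignment, ref_grid)
  et <- transfer_energy(dose_moving, mass_image, alignment)
  vals <- map_pull_cpp(pull_table$ranges, pull_table$source_index,
                       pull_table$dXb, et, ref_grid$shape, as.integer(n_slabs),
                       precision == "single")
  finish_energy(vals, ref_grid, sum(et[pull_table$source_index + 1]), "energy")
}

#' Map phase energy to the reference grid (unified branch-free layout)
#'
#' Same gather contract as [map_energy_pull()], but records are keyed by the
#' minimum-index corner of their overlap ensemble and the 8 weights are the
#' ordered products over `{w0, 1 - w0}` per axis -- one fixed pattern, no
#' conditional branching on offset signs.
#'
#' @inheritParams map_energy_pull
#' @param unified_table a `dvs_unified` table from [compile_unified()].
#' @return energy [scalar_volume()] on `ref_grid` (Gy g).
#' @export
map_energy_unified <- function(dose_moving, mass_image, unified_table,
                               alignment, ref_grid, n_slabs = 1L,
                               precision = c("double", "single")) {
  precision <- match.arg(precision)
  stopifnot(inherits(unified_table, "dvs_unified"))
  check_mapping_inputs(dose_moving, mass_image, unified_table, alignment, ref_grid)
  et <- transfer_energy(dose_moving, mass_image, alignment)
  vals <- map_unified_cpp(unified_table$ranges, unified_table$source_index,
                          unified_table$wb, et, ref_grid$shape,
                          as.integer(n_slabs), precision == "single")
  finish_energy(vals, ref_grid, sum(et[unified_table$source_index + 1]), "energy")
}

#' Map per-image-voxel mass to the reference grid
#'
#' The same scatter applied to mass instead of energy; the transferred-mass
#' volume depends only on the phase geometry, so it is computed once per
#' phase and cached (see [precompute_phase_bundles()]). Dispatches on the
#' table layout.
#'
#' @param mass_image per-image-voxel mass [scalar_volume()] (g).
#' @param table any compiled DVS table.
#' @param ref_grid the reference [grid3d()].
#' @param n_slabs z-slab count for the pull/unified gathers.
#' @param precision `"double"` or `"single"`.
#' @return mass [scalar_volume()] on `ref_grid` (g), with `total_in` and
#'   `conservation_residual` attributes.
#' @export
map_mass <- function(mass_image, table, ref_grid, n_slabs = 1L,
                     precision = c("double", "single")) {
  precision <- match.arg(precision)
  stopifnot(inherits(table, "dvs_table"), inherits(mass_image, "scalar_volume"))
  if (mass_image$role != "mass") stop("map_mass: input role must be 'mass'")
  if (!all(table$image_shape == mass_image$grid$shape))
    stop("map_mass: table was compiled for a different image grid")
  if (!all(table$ref_shape == ref_grid$shape))
    stop("map_mass: table was compiled for a different reference grid")
  m <- mass_image$values
  single <- precision == "single"
  if (table$layout == "push") {
    vals <- map_push_cpp(table$target_index, table$dXb, table$is_used, m,
                         ref_grid$shape, single)
    tot <- sum(m[table$is_used != 0L])
  } else if (table$layout == "pull") {
    vals <- map_pull_cpp(table$ranges, table$source_index, table$dXb, m,
                         ref_grid$shape, as.integer(n_slabs), single)
    tot <- sum(m[table$source_index + 1])
  } else {
    vals <- map_unified_cpp(table$ranges, table$source_index, table$wb, m,
                            ref_grid$shape, as.integer(n_slabs), single)
    tot <- sum(m[table$source_index + 1])
  }
  finish_energy(vals, ref_grid, tot, "mass")
}

#' Accumulated dose from transferred energy and mass
#'
#' `D(v) = E(v) / M(v)` wherever the transferred mass reaches `mass_floor`;
#' voxels below the floor get dose 0 and are counted in the `floored_voxels`
#' attribute. The floor guards against division blow-up where (numerically)
#' no mass was transported.
#'
#' @param energy energy [scalar_volume()] (Gy g) on the reference grid.
#' @param mass mass [scalar_volume()] (g) on the same grid.
#' @param mass_floor minimum mass (g), default `1e-6`.
#' @return dose [scalar_volume()] (Gy) with attribute `floored_voxels`.
#' @export
divide_energy_by_mass <- function(energy, mass, mass_floor = 1e-6) {
  stopifnot(inherits(energy, "scalar_volume"), inherits(mass, "scalar_volume"))
  if (!grids_equal(energy$grid, mass$grid))
    stop("divide_energy_by_mass: energy and mass must share the reference grid")
  if (any(energy$values < 0) || any(mass$values < 0))
    stop("divide_energy_by_mass: negative inputs")
  ok <- mass$values >= mass_floor
  d <- numeric(length(energy$values))
  d[ok] <- energy$values[ok] / mass$values[ok]
  out <- scalar_volume(energy$grid, d, role = "dose")
  attr(out, "floored_voxels") <- sum(!ok)
  out
}

#' Direct dose mapping baseline
#'
#' Accumulates the weighted mean of contributing source dose values per
#' reference voxel, `D(v) = sum(w d) / sum(w)`, using the same trilinear
#' overlap weights as EMT so that the difference to EMT isolates the
#' averaging-vs-energy/mass distinction. Voxels receiving no weight get 0.
#' Under tissue compression DDM averages doses while EMT forms the
#' mass-weighted mean, which is the mechanism behind their disagreement in
#' heterogeneous, steep-gradient regions.
#'
#' @inheritParams map_energy_push
#' @return dose [scalar_volume()] on `ref_grid` (Gy), with the summed weight
#'   per voxel in attribute `weight_sum`.
#' @export
ddm_map <- function(dose_moving, push_records, alignment, ref_grid) {
  stopifnot(inherits(push_records, "dvs_push"))
  check_mapping_inputs(dose_moving, NULL, push_records, alignment, ref_grid)
  d_img <- dose_moving$values[image_to_dose_map(alignment) + 1]
  res <- map_ddm_cpp(push_records$target_index, push_records$dXb,
                     push_records$is_used, d_img, ref_grid$shape)
  out <- scalar_volume(ref_grid, res$dose, role = "dose")
  attr(out, "weight_sum") <- res$weight
  out
}
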