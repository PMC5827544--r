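# Shared in-code fixtures: tiny grids, random volumes/fields and a pure-R
# scatter reference used as an independent oracle for the C++ kernels.

# identical image/dose/reference grids (ratio 1:1:1)
identity_setup <- function(shape = c(6, 6, 6), spacing = c(1, 1, 1)) {
  g <- grid3d(origin = c(0, 0, 0), spacing = spacing, shape = shape)
  list(grid = g, alignment = grid_alignment(g, g))
}

# clinical-style 2:2:1 image-to-dose relation at toy size
coarse_setup <- function(image_shape = c(8, 8, 6)) {
  ig <- grid3d(origin = c(0, 0, 0), spacing = c(1, 1, 2), shape = image_shape)
  dg <- grid3d(origin = c(0.5, 0.5, 0), spacing = c(2, 2, 2),
               shape = image_shape %/% c(2L, 2L, 1L))
  list(image_grid = ig, dose_grid = dg, alignment = grid_alignment(ig, dg))
}

rand_volume <- function(grid, role = "dose", seed = 1, max = 1) {
  set.seed(seed)
  scalar_volume(grid, runif(prod(grid$shape), 0, max), role = role)
}

zero_dvf <- function(grid) {
  displacement_field(grid, matrix(0, prod(grid$shape), 3))
}

rand_dvf <- function(grid, seed = 1, sd_mm = 1.5) {
  set.seed(seed)
  displacement_field(grid, matrix(rnorm(3 * prod(grid$shape), 0, sd_mm), ncol = 3))
}

small_phantom <- function(seed = 1) {
  phantom_spec(image_shape = c(16L, 16L, 12L), n_phases = 4L,
               amplitude_mm = 4, trajectory_semiaxes_mm = c(1, 0.5, 4),
               beam_sigma_mm = 4, seed = seed)
}

# Pure-R push scatter used as an independent reference: trilinear overlap
# weights evaluated per record from (possibly unquantized) offsets, looped
# record by record. dx is an n x 3 matrix of relative offsets, nearest an
# n x 3 matrix of 0-based nearest-voxel ijk.
r_scatter_reference <- function(nearest, dx, used, et, ref_grid) {
  acc <- numeric(prod(ref_grid$shape))
  for (k in seq_along(et)) {
    if (!used[k]) next
    ow <- overlap_weights(dx[k, ], nearest[k, ], grid = ref_grid)
    acc[ow$flat + 1] <- acc[ow$flat + 1] + ow$weights * et[k]
  }
  acc
}

# decompose push records back into nearest ijk for the R reference
push_nearest_ijk <- function(push, ref_grid) {
  ijk_index(ref_grid, push$target_index)
}

# align overlap_weights output with the 27-neighbour oracle by integer offset
merge_weights_by_offset <- function(w, orc, base = c(1L, 1L, 1L)) {
  key <- function(m) m[, 1] * 9 + m[, 2] * 3 + m[, 3]
  idx <- match(key(sweep(w$voxels, 2, base, `-`)), key(orc$offsets))
  list(w = w$weights, orc = orc$weights[idx])
}
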