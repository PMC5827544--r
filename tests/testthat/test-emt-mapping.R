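test_that("overlap weights partition the unit voxel", {
  g <- grid3d(shape = c(5, 5, 5))

  w0 <- overlap_weights(c(0, 0, 0), c(2, 2, 2), grid = g)
  expect_equal(w0$weights[1], 1)
  expect_true(all(w0$weights[-1] == 0))
  expect_identical(w0$voxels[1, ], c(2L, 2L, 2L))

  wh <- overlap_weights(c(0.5, 0.5, 0.5), c(2, 2, 2))
  expect_equal(wh$weights, rep(0.125, 8))

  # 2D slice: offsets (0.25, 0.4, 0)
  w2 <- overlap_weights(c(0.25, 0.4, 0), c(2, 2, 2))
  wt <- function(di, dj, dk) {
    hit <- apply(w2$voxels, 1, function(v) all(v == c(2 + di, 2 + dj, 2 + dk)))
    w2$weights[hit]
  }
  expect_equal(wt(0, 0, 0), 0.45)   # nearest voxel: 0.75 * 0.6
  expect_equal(wt(1, 0, 0), 0.15)
  expect_equal(wt(0, 1, 0), 0.30)
  expect_equal(wt(1, 1, 0), 0.10)   # diagonal neighbour
  expect_true(all(abs(w2$weights[5:8]) < 1e-15))  # z layer untouched

  expect_error(overlap_weights(c(0.6, 0, 0)), "offsets")
})

test_that("overlap weights agree with the box-intersection oracle", {
  set.seed(41)
  for (rep in 1:500) {
    dx <- runif(3, -0.5, 0.5)
    dx[dx == -0.5] <- 0.5
    ow <- overlap_weights(dx, c(1, 1, 1))
    orc <- box_intersection_oracle(dx)
    expect_equal(sum(orc$weights), 1, tolerance = 1e-12)
    for (j in 1:8) {
      d <- ow$voxels[j, ] - c(1L, 1L, 1L)
      hit <- which(apply(orc$offsets, 1, identical, d))
      expect_equal(ow$weights[j], orc$weights[hit], tolerance = 1e-12)
    }
    # no oracle mass outside the 8-voxel ensemble
    expect_equal(sum(orc$weights), sum(ow$weights), tolerance = 1e-12)
  }

  half <- box_intersection_oracle(c(0.5, 0, 0))
  expect_identical(sort(half$weights[half$weights > 0]), c(0.5, 0.5))
})

transfer_energy_for_test <- function(dose, mass, alignment) {
  idx <- flat_index(alignment$dose_grid,
                    containing_dose_voxel(
                      ijk_index(alignment$image_grid,
                                seq_along(mass$values) - 1), alignment))
  dose$values[idx + 1] * mass$values
}

new_push_for_test <- function(push, used) {
  push$is_used <- as.integer(used)
  push
}

# single engineered displacement on identity grids, optionally masked
single_record_setup <- function(dx_voxel = c(0, 0, 0), d_gy = 2,
                                rho = 0.5, shape = c(6, 6, 6)) {
  idy <- identity_setup(shape = shape, spacing = c(1, 1, 2))
  g <- idy$grid
  n <- prod(g$shape)
  src <- flat_index(g, c(2, 2, 2))
  vec <- matrix(0, n, 3)
  vec[src + 1, ] <- dx_voxel * g$spacing
  mask <- rep(FALSE, n); mask[src + 1] <- TRUE
  push <- compile_push(displacement_field(g, vec), g, mask = mask)
  dose <- scalar_volume(g, rep(d_gy, n), "dose")
  mass <- image_voxel_mass(scalar_volume(g, rep(rho, n), "density"))
  list(grid = g, alignment = idy$alignment, push = push, dose = dose,
       mass = mass, src = src)
}

test_that("push mapping scatters E_T = d * m with trilinear weights", {
  s <- single_record_setup(c(0, 0, 0), d_gy = 2, rho = 0.5)  # m = 0.001 g
  e <- map_energy_push(s$dose, s$mass, s$push, s$alignment, s$grid)
  expect_equal(sum(e$values > 0), 1L)
  expect_equal(max(e$values), 0.002)                 # 2 Gy * 0.001 g
  expect_equal(attr(e, "conservation_residual"), 0)

  # half-voxel offset on all axes: 8 near-equal shares (equal up to the
  # signed 8-bit code 64/127 standing in for 0.5), energy conserved exactly
  s8 <- single_record_setup(c(0.5, 0.5, 0.5), d_gy = 2, rho = 0.5)
  e8 <- map_energy_push(s8$dose, s8$mass, s8$push, s8$alignment, s8$grid)
  expect_equal(sum(e8$values > 0), 8L)
  expect_equal(e8$values[e8$values > 0], rep(0.00025, 8), tolerance = 0.03)
  expect_equal(sum(e8$values), 0.002, tolerance = 1e-14)

  z <- single_record_setup(c(0.2, 0, 0), d_gy = 0)
  ez <- map_energy_push(z$dose, z$mass, z$push, z$alignment, z$grid)
  expect_true(all(ez$values == 0))
})

test_that("all three layouts give equivalent energy maps", {
  setup <- coarse_setup(image_shape = c(10, 10, 8))
  dvf <- rand_dvf(setup$image_grid, seed = 17, sd_mm = 2)
  push <- compile_push(dvf, setup$dose_grid)
  pull <- compile_pull(push, setup$dose_grid)
  uni <- compile_unified(push, setup$dose_grid)
  dose <- rand_volume(setup$dose_grid, "dose", seed = 18, max = 3)
  mass <- image_voxel_mass(rand_volume(setup$image_grid, "density", seed = 19))

  ep <- map_energy_push(dose, mass, push, setup$alignment, setup$dose_grid)
  el <- map_energy_pull(dose, mass, pull, setup$alignment, setup$dose_grid)
  eu <- map_energy_unified(dose, mass, uni, setup$alignment, setup$dose_grid)

  nz <- ep$values != 0
  expect_true(max(abs(el$values[nz] - ep$values[nz]) / ep$values[nz]) <= 1e-12)
  expect_true(max(abs(eu$values[nz] - ep$values[nz]) / ep$values[nz]) <= 1e-12)
  expect_true(all(el$values[!nz] == 0), info = "no energy outside push support")

  # slab decomposition changes nothing, bitwise
  el4 <- map_energy_pull(dose, mass, pull, setup$alignment, setup$dose_grid,
                         n_slabs = 4)
  expect_identical(el4$values, el$values)
  eu3 <- map_energy_unified(dose, mass, uni, setup$alignment, setup$dose_grid,
                            n_slabs = 3)
  eu8 <- map_energy_unified(dose, mass, uni, setup$alignment, setup$dose_grid,
                            n_slabs = 8)
  expect_identical(eu3$values, eu$values)
  expect_identical(eu8$values, eu$values)
  expect_error(map_energy_pull(dose, mass, pull, setup$alignment,
                               setup$dose_grid, n_slabs = 1000), "n_slabs")

  # and the C++ scatter agrees with a pure-R trilinear reference
  et <- dose$values[flat_index(setup$dose_grid,
                               containing_dose_voxel(
                                 ijk_index(setup$image_grid,
                                           seq_along(mass$values) - 1),
                                 setup$alignment)) + 1] * mass$values
  ref <- r_scatter_reference(push_nearest_ijk(push, setup$dose_grid),
                             matrix(dequantize_offset(push$dXb), ncol = 3),
                             push$is_used == 1L, et, setup$dose_grid)
  expect_equal(ep$values, ref, tolerance = 1e-12)
})

test_that("energy and mass are conserved by every layout", {
  setup <- coarse_setup(image_shape = c(10, 10, 8))
  for (seed in c(2, 23)) {
    push <- compile_push(rand_dvf(setup$image_grid, seed = seed, sd_mm = 2.5),
                         setup$dose_grid)
    pull <- compile_pull(push, setup$dose_grid)
    uni <- compile_unified(push, setup$dose_grid)
    dose <- rand_volume(setup$dose_grid, "dose", seed = seed + 1, max = 2)
    mass <- image_voxel_mass(rand_volume(setup$image_grid, "density",
                                         seed = seed + 2))
    for (res in list(
      map_energy_push(dose, mass, push, setup$alignment, setup$dose_grid),
      map_energy_pull(dose, mass, pull, setup$alignment, setup$dose_grid, 2),
      map_energy_unified(dose, mass, uni, setup$alignment, setup$dose_grid, 2),
      map_mass(mass, push, setup$dose_grid),
      map_mass(mass, pull, setup$dose_grid),
      map_mass(mass, uni, setup$dose_grid))) {
      expect_lte(attr(res, "conservation_residual"), 1e-12)
    }
  }
})

test_that("identity field with 1:1 grids reproduces the moving dose", {
  idy <- identity_setup(shape = c(6, 6, 6), spacing = c(1, 1, 2))
  g <- idy$grid
  push <- compile_push(zero_dvf(g), g)
  dose <- rand_volume(g, "dose", seed = 29, max = 4)
  mass <- image_voxel_mass(rand_volume(g, "density", seed = 30, max = 1.5))
  e <- map_energy_push(dose, mass, push, idy$alignment, g)
  m <- map_mass(mass, push, g)
  d <- divide_energy_by_mass(e, m, mass_floor = 1e-9)
  ok <- m$values > 1e-9
  expect_equal(d$values[ok], dose$values[ok], tolerance = 1e-12)
  # mass maps through unchanged where used
  used <- push$is_used == 1L
  expect_equal(m$values[used], mass$values[used], tolerance = 1e-12)
})

test_that("constant integer-voxel translation shifts the dose field", {
  idy <- identity_setup(shape = c(7, 6, 5))
  g <- idy$grid
  n <- prod(g$shape)
  shift <- c(1L, -2L, 1L)
  vec <- matrix(rep(shift * g$spacing, each = n), n, 3)
  push <- compile_push(displacement_field(g, vec), g)
  dose <- rand_volume(g, "dose", seed = 37, max = 2)
  mass <- image_voxel_mass(rand_volume(g, "density", seed = 38))
  d <- divide_energy_by_mass(
    map_energy_push(dose, mass, push, idy$alignment, g),
    map_mass(mass, push, g), mass_floor = 1e-12)

  src_ijk <- ijk_index(g, seq_len(n) - 1)
  dst_ijk <- sweep(src_ijk, 2, shift, `+`)
  inside <- push$is_used == 1L
  dst <- flat_index(g, dst_ijk[inside, ])
  expect_equal(d$values[dst + 1], dose$values[inside], tolerance = 1e-12)
})

test_that("compression: EMT is the mass-weighted mean, DDM the plain mean", {
  build_compression <- function(d1, d2, rho1, rho2) {
    idy <- identity_setup(shape = c(6, 6, 6), spacing = c(1, 1, 2))
    g <- idy$grid
    n <- prod(g$shape)
    a <- flat_index(g, c(2, 2, 3)); b <- flat_index(g, c(2, 2, 2))
    vec <- matrix(0, n, 3)
    vec[a + 1, 3] <- -g$spacing[3]             # a collapses onto b
    mask <- rep(FALSE, n); mask[c(a, b) + 1] <- TRUE
    push <- compile_push(displacement_field(g, vec), g, mask = mask)
    dvals <- numeric(n); dvals[b + 1] <- d2; dvals[a + 1] <- d1
    rvals <- numeric(n); rvals[b + 1] <- rho2; rvals[a + 1] <- rho1
    dose <- scalar_volume(g, dvals, "dose")
    mass <- image_voxel_mass(scalar_volume(g, rvals, "density"))
    emt <- divide_energy_by_mass(
      map_energy_push(dose, mass, push, idy$alignment, g),
      map_mass(mass, push, g), mass_floor = 1e-12)
    ddm <- ddm_map(dose, push, idy$alignment, g)
    c(emt = emt$values[b + 1], ddm = ddm$values[b + 1])
  }

  # canonical case: masses (0.001, 0.003) g, doses (1, 2) Gy (V_A = 0.002 cm^3)
  res <- build_compression(d1 = 1, d2 = 2, rho1 = 0.5, rho2 = 1.5)
  expect_equal(res[["emt"]], 1.75, tolerance = 1e-12)
  expect_equal(res[["ddm"]], 1.5, tolerance = 1e-12)

  set.seed(43)
  for (rep in 1:10) {
    d <- runif(2, 0.5, 3); rho <- runif(2, 0.2, 2)
    m <- rho * 0.002
    res <- build_compression(d[1], d[2], rho[1], rho[2])
    expect_equal(res[["emt"]], sum(m * d) / sum(m), tolerance = 1e-12)
    expect_equal(res[["ddm"]], mean(d), tolerance = 1e-12)
    if (abs(m[1] - m[2]) > 1e-6 && abs(d[1] - d[2]) > 1e-6)
      expect_gt(abs(res[["emt"]] - res[["ddm"]]), 1e-12)
  }
})

test_that("DDM maps identity and uniform fields faithfully", {
  idy <- identity_setup()
  g <- idy$grid
  push <- compile_push(zero_dvf(g), g)
  dose <- rand_volume(g, "dose", seed = 47, max = 2)
  dd <- ddm_map(dose, push, idy$alignment, g)
  mapped <- attr(dd, "weight_sum") > 0
  expect_equal(dd$values[mapped], dose$values[mapped], tolerance = 1e-12)

  uni_dose <- scalar_volume(g, rep(1.3, prod(g$shape)), "dose")
  du <- ddm_map(uni_dose, push, idy$alignment, g)
  expect_equal(unique(round(du$values[mapped], 12)), 1.3)
  expect_true(all(du$values[!mapped] == 0))
})

test_that("energy-by-mass division applies the floor and counts it", {
  g <- grid3d(shape = c(2, 2, 1))
  e <- scalar_volume(g, c(0.002, 0.004, 0, 0.001), "energy")
  m <- scalar_volume(g, c(0.001, 0.002, 0, 1e-9), "mass")
  d <- divide_energy_by_mass(e, m, mass_floor = 1e-6)
  expect_equal(d$values, c(2, 2, 0, 0))
  expect_identical(attr(d, "floored_voxels"), 2L)
  expect_error(divide_energy_by_mass(e, scalar_volume(grid3d(shape = c(4, 1, 1)),
                                                      rep(1, 4), "mass")),
               "reference grid")
})

test_that("quantization perturbs the energy map by at most 3/254 per unit transfer", {
  setup <- coarse_setup(image_shape = c(8, 8, 6))
  dvf <- rand_dvf(setup$image_grid, seed = 53, sd_mm = 2)
  push <- compile_push(dvf, setup$dose_grid)
  dose <- rand_volume(setup$dose_grid, "dose", seed = 54, max = 2)
  mass <- image_voxel_mass(rand_volume(setup$image_grid, "density", seed = 55))
  et <- transfer_energy_for_test(dose, mass, setup$alignment)

  # exact (unquantized) offsets from the same geometry
  g <- setup$image_grid
  ijk <- ijk_index(g, seq_len(prod(g$shape)) - 1)
  p <- voxel_centre(g, ijk) + dvf$vectors
  t_rel <- sweep(sweep(p, 2, setup$dose_grid$origin, `-`), 2,
                 setup$dose_grid$spacing, `/`)
  nearest <- ceiling(t_rel - 0.5)
  dx_exact <- t_rel - nearest
  # keep records whose exact AND quantized ensembles are both in-grid
  base_exact <- nearest + ifelse(dx_exact < 0, -1, 0)
  in_exact <- rowSums(base_exact >= 0) == 3L &
    rowSums(sweep(base_exact + 1, 2, setup$dose_grid$shape - 1L, `<=`)) == 3L
  used <- push$is_used == 1L & in_exact

  e_exact <- r_scatter_reference(nearest, dx_exact, used, et, setup$dose_grid)
  e_quant <- map_energy_push(
    dose, mass,
    new_push_for_test(push, used), setup$alignment, setup$dose_grid)
  # per-voxel envelope: total E_T whose ensemble touches the voxel; a
  # record's weights are each perturbed by at most 3 * (1/254)
  envelope_et <- numeric(prod(setup$dose_grid$shape))
  for (k in which(used)) {
    ow <- overlap_weights(dx_exact[k, ], nearest[k, ], grid = setup$dose_grid)
    envelope_et[ow$flat + 1] <- envelope_et[ow$flat + 1] + et[k]
  }
  expect_true(all(abs(e_quant$values - e_exact) <=
                    3 / 254 * envelope_et + 1e-15))
})
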