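test_that("offset quantization matches the signed 8-bit code table", {
  # exhaustive oracle over all 255 codes: dequantize -> quantize is identity
  codes <- -127:127
  expect_identical(quantize_offset(dequantize_offset(codes)), codes)

  expect_identical(quantize_offset(0), 0L)
  expect_identical(quantize_offset(0.5), 64L)       # ties away from zero
  expect_identical(quantize_offset(-0.25), -32L)
  expect_equal(dequantize_offset(64L), 64 / 127)
  expect_equal(dequantize_offset(-32L), -32 / 127)

  set.seed(21)
  x <- runif(5000, -1, 1)
  err <- abs(dequantize_offset(quantize_offset(x)) - x)
  expect_true(all(err <= 1 / 254 + 1e-15))
  expect_identical(sign(dequantize_offset(quantize_offset(x))),
                   sign(quantize_offset(x)))        # sign preserved
  expect_error(quantize_offset(1.2), "within")
})

test_that("push compilation stores nearest voxel, quantized offset and usage", {
  idy <- identity_setup(shape = c(6, 6, 6))
  g <- idy$grid
  n <- prod(g$shape)

  push0 <- compile_push(zero_dvf(g), g)
  # identity displacement at an interior voxel: own index, zero offset, used
  v <- flat_index(g, c(2, 3, 2))
  k <- v + 1
  expect_identical(push0$target_index[k], as.integer(v))
  expect_identical(push0$dXb[k, ], c(0L, 0L, 0L))
  expect_identical(push0$is_used[k], 1L)

  # +half a reference spacing along axis 1: tie resolves to offset +0.5
  vec <- matrix(0, n, 3); vec[, 1] <- 0.5 * g$spacing[1]
  push_h <- compile_push(displacement_field(g, vec), g)
  expect_identical(push_h$target_index[k], as.integer(v))  # lower voxel keeps it
  expect_identical(push_h$dXb[k, 1], 64L)                  # quantize(+0.5)

  # displaced far outside the reference volume: flagged unused
  vec <- matrix(0, n, 3); vec[, 3] <- 100
  push_out <- compile_push(displacement_field(g, vec), g)
  expect_true(all(push_out$is_used == 0L))
  expect_true(all(push_out$target_index >= 0 & push_out$target_index < n))

  # mask wins over geometry
  mask <- rep(FALSE, n); mask[k] <- TRUE
  pm <- compile_push(zero_dvf(g), g, mask = mask)
  expect_identical(sum(pm$is_used), 1L)
  expect_identical(which(pm$is_used == 1L), as.integer(k))

  expect_error(compile_push(zero_dvf(g), grid3d(shape = c(2, 2, 2)),
                            mask = rep(TRUE, 5)), "mask length")
})

test_that("used offsets stay within half a voxel for random fields", {
  setup <- coarse_setup()
  for (seed in 1:3) {
    push <- compile_push(rand_dvf(setup$image_grid, seed = seed, sd_mm = 3),
                         setup$dose_grid)
    dx <- dequantize_offset(push$dXb[push$is_used == 1L, ])
    expect_true(all(abs(dx) <= 0.5 + 1 / 254 + 1e-12))
  }
})

test_that("pull re-keying preserves the record multiset per reference voxel", {
  setup <- coarse_setup()
  push <- compile_push(rand_dvf(setup$image_grid, seed = 7, sd_mm = 2),
                       setup$dose_grid)
  pull <- compile_pull(push, setup$dose_grid)

  expect_identical(length(pull$source_index), sum(push$is_used == 1L))
  expect_true(all(diff(pull$ranges) >= 0L))
  expect_identical(pull$ranges[length(pull$ranges)],
                   length(pull$source_index))

  # every record sits in the range of its own target voxel, ascending source
  counts <- diff(pull$ranges)
  voxel_of_record <- rep(seq_along(counts) - 1L, counts)
  used <- which(push$is_used == 1L)
  expect_identical(sort(pull$source_index), sort(used - 1L))
  m_push <- cbind(used - 1L, push$target_index[used], push$dXb[used, ],
                  deparse.level = 0)
  m_pull <- cbind(pull$source_index, voxel_of_record, pull$dXb,
                  deparse.level = 0)
  expect_identical(m_pull[order(m_pull[, 1]), ], m_push[order(m_push[, 1]), ])
  # within-voxel order is ascending source index
  expect_true(all(tapply(pull$source_index, voxel_of_record,
                         function(s) all(diff(s) > 0))))

  # a voxel targeted by no displacement has an empty range
  hit <- tabulate(push$target_index[used] + 1L, nbins = prod(setup$dose_grid$shape))
  expect_true(all(counts[hit == 0L] == 0L))

  # two displacements engineered into one reference voxel share its range
  idy <- identity_setup()
  n <- prod(idy$grid$shape)
  vec <- matrix(0, n, 3)
  a <- flat_index(idy$grid, c(2, 2, 3)); b <- flat_index(idy$grid, c(2, 2, 2))
  vec[a + 1, 3] <- -idy$grid$spacing[3]       # voxel a lands on voxel b
  mask <- rep(FALSE, n); mask[c(a, b) + 1] <- TRUE
  p2 <- compile_pull(compile_push(displacement_field(idy$grid, vec), idy$grid,
                                  mask = mask), idy$grid)
  expect_identical(diff(p2$ranges)[b + 1], 2L)
})

test_that("unified re-keying uses the minimum-index corner and w0 factors", {
  # offsets (0.25, -0.4, 0.1): base steps (0, -1, 0), w0 = (0.75, 0.4, 0.9)
  uf <- unified_weight_factors(c(0.25, -0.4, 0.1))
  expect_identical(uf$base_offset, c(0L, -1L, 0L))
  expect_equal(uf$w0, c(0.75, 0.4, 0.9))

  # zero offset: base is the nearest voxel and all energy stays on it
  uf0 <- unified_weight_factors(c(0, 0, 0))
  expect_identical(uf0$base_offset, c(0L, 0L, 0L))
  expect_equal(uf0$w0, c(1, 1, 1))

  # through the compiler, at quantized precision
  idy <- identity_setup(shape = c(7, 7, 7))
  g <- idy$grid
  n <- prod(g$shape)
  vec <- matrix(0, n, 3)
  k <- flat_index(g, c(3, 3, 3)) + 1
  vec[k, ] <- c(0.25, -0.4, 0.1) * g$spacing
  mask <- rep(FALSE, n); mask[k] <- TRUE
  push <- compile_push(displacement_field(g, vec), g, mask = mask)
  uni <- compile_unified(push, g)
  expect_identical(length(uni$source_index), 1L)
  base_voxel <- which(diff(uni$ranges) == 1L) - 1L
  expect_identical(base_voxel, as.integer(flat_index(g, c(3, 2, 3))))
  expect_equal(dequantize_offset(uni$wb[1, ]), c(0.75, 0.4, 0.9),
               tolerance = 1 / 127)

  # the 8 products over {w0, 1 - w0} always sum to 1
  set.seed(31)
  for (rep in 1:20) {
    w0 <- runif(3)
    prods <- apply(as.matrix(expand.grid(0:1, 0:1, 0:1)), 1,
                   function(o) prod(ifelse(o == 1, 1 - w0, w0)))
    expect_equal(sum(prods), 1, tolerance = 1e-12)
  }
})

test_that("push and unified records describe the same weighted voxel set", {
  setup <- coarse_setup()
  push <- compile_push(rand_dvf(setup$image_grid, seed = 13, sd_mm = 2),
                       setup$dose_grid)
  uni <- compile_unified(push, setup$dose_grid)
  rg <- setup$dose_grid
  counts <- diff(uni$ranges)
  base_of_record <- rep(seq_along(counts) - 1L, counts)

  used <- which(push$is_used == 1L)
  # order unified records by source to line them up with push records
  ord <- order(uni$source_index)
  expect_identical(uni$source_index[ord], used - 1L)

  for (pick in seq(1, length(used), length.out = 25)) {
    j <- ord[round(pick)]
    k <- uni$source_index[j] + 1L
    dx <- dequantize_offset(push$dXb[k, ])
    ow <- overlap_weights(dx, ijk_index(rg, push$target_index[k])[1, ], grid = rg)
    # same base corner
    expect_identical(base_of_record[j], as.integer(ow$flat[1]))
    # same 8 weights, reproduced from the stored w0 factors exactly
    w0 <- dequantize_offset(uni$wb[j, ])
    prods <- apply(as.matrix(expand.grid(0:1, 0:1, 0:1)), 1,
                   function(o) prod(ifelse(o == 1, 1 - w0, w0)))
    expect_equal(prods, ow$weights, tolerance = 1e-12)
  }
})
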