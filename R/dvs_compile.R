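# Compile a displacement field into the three displacement-vector-structure
# (DVS) layouts:
#   push    -- one record per moving image voxel, keyed by the nearest
#              reference voxel to the displaced point (serial scatter);
#   pull    -- the same records re-keyed per reference voxel so each voxel's
#              contributions are gathered by one worker (parallel-safe);
#   unified -- re-keyed by the minimum-index corner of the 8-voxel overlap
#              ensemble, with per-axis weight factors w0, so the 8 overlap
#              weights follow one fixed branch-free pattern.
# Offsets and weight factors are stored as signed 8-bit integers, dequantized
# by 2^7 - 1 = 127.

#' Quantize / dequantize a relative offset to signed 8 bits
#'
#' `b = round(x * 127)` with ties rounded half away from zero (so the sign of
#' the code always equals the sign of the offset, which selects the overlap
#' quadrant); the floating-point value is recovered as `b / (2^7 - 1)`. The
#' round trip error is at most `1/254`.
#'
#' @param x numeric in `[-1, 1]` (relative voxel coordinates).
#' @param b integer codes in `[-127, 127]`.
#' @return `quantize_offset`: integer codes; `dequantize_offset`: numeric.
#' @examples
#' quantize_offset(c(0, 0.5, -0.25))       # 0, 64, -32
#' dequantize_offset(quantize_offset(0.5)) # 64/127
#' @export
quantize_offset <- function(x) {
  if (any(!is.finite(x)) || any(abs(x) > 1))
    stop("quantize_offset: offsets must be finite and within [-1, 1]")
  as.integer(sign(x) * floor(abs(x) * 127 + 0.5))
}

#' @rdname quantize_offset
#' @export
dequantize_offset <- function(b) {
  as.numeric(b) / 127
}

#' Branch-free weight factors from a relative offset
#'
#' Re-parameterizes an offset \eqn{\Delta\bar x_i \in (-0.5, 0.5]} relative
#' to the nearest voxel into the unified-pattern form: the base ("voxel 1")
#' is the minimum-index corner of the 8-voxel overlap ensemble,
#' `base = nearest - 1` on axes with negative offset, and the base weight
#' factor is `w0 = |dx|` there and `w0 = 1 - dx` otherwise; a `+1` step along
#' axis i swaps `w0` for `w+ = 1 - w0`. The base voxel's overlap volume is
#' `w0[1] * w0[2] * w0[3]`.
#'
#' @param dxbar numeric vector or n x 3 matrix of relative offsets.
#' @return list with `w0` (same shape) and `base_offset` (0 or -1 per axis,
#'   relative to the nearest voxel).
#' @export
unified_weight_factors <- function(dxbar) {
  neg <- dxbar < 0
  w0 <- ifelse(neg, -dxbar, 1 - dxbar)
  list(w0 = w0, base_offset = ifelse(neg, -1L, 0L))
}

#' Compile a displacement field into push-layout DVS records
#'
#' Emits one record per moving image voxel, in ascending flat image-voxel
#' order. The displaced target point is `p = voxel centre + vector`; the
#' nearest reference voxel is chosen per axis with the half-integer tie
#' broken so the stored offset lies in `(-0.5, 0.5]`; the offset of `p` from
#' that voxel's centre (in reference voxel units) is quantized to signed
#' 8 bits. Records whose full 8-voxel overlap ensemble (determined from the
#' quantized offset) is not completely inside the reference grid are flagged
#' unused rather than clipped, which keeps energy conservation exact for
#' every used record; their count is available as `sum(!table$is_used)`.
#'
#' @param dvf a [displacement_field()] on the moving image grid (vectors map
#'   voxel centres to reference-space points, mm).
#' @param ref_grid the reference [grid3d()] (energy grid).
#' @param mask optional per-image-voxel region of interest (logical or 0/1
#'   vector in flat order); masked-out voxels are flagged unused.
#' @return a `dvs_push` table.
#' @export
compile_push <- function(dvf, ref_grid, mask = NULL) {
  stopifnot(inherits(dvf, "displacement_field"), inherits(ref_grid, "grid3d"))
  n <- n_voxels(dvf$grid)
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != n)
      stop("compile_push: mask length must equal the image voxel count")
  } else mask <- rep(TRUE, n)

  ijk <- ijk_index(dvf$grid, seq_len(n) - 1)
  p <- voxel_centre(dvf$grid, ijk) + dvf$vectors
  t_rel <- sweep(sweep(p, 2, ref_grid$origin, `-`), 2, ref_grid$spacing, `/`)
  nearest <- ceiling(t_rel - 0.5)            # tie at +0.5 stays with the lower voxel
  dx <- t_rel - nearest                      # in (-0.5, 0.5]
  dXb <- matrix(quantize_offset(dx), ncol = 3L)

  # overlap ensemble from the quantized offset (what the kernels will use)
  base <- nearest + ifelse(dXb < 0L, -1, 0)
  inside <- rowSums(base >= 0) == 3L &
    rowSums(sweep(base + 1, 2, ref_grid$shape - 1L, `<=`)) == 3L
  used <- mask & inside

  clamped <- pmin(pmax(nearest, 0), matrix(ref_grid$shape - 1L, n, 3L, byrow = TRUE))
  new_dvs_push(target_index = flat_index(ref_grid, clamped),
               dXb = dXb, is_used = as.integer(used),
               image_shape = dvf$grid$shape, ref_shape = ref_grid$shape)
}

#' Re-key push records per reference voxel (pull layout)
#'
#' Drops unused records and arranges the rest contiguously per target
#' reference voxel (ascending source index within a voxel), replacing the
#' target index by the source image-voxel index. The status byte disappears:
#' a pull record exists only if it is used. The per-voxel record ranges are
#' stored as `ranges` (cumulative counts, length = reference voxel count
#' + 1), so voxel `v`'s records are `(ranges[v+1] + 1):ranges[v+2]` in R
#' indexing.
#'
#' @param push_records a `dvs_push` table from [compile_push()].
#' @param ref_grid the reference [grid3d()] used to compile it.
#' @return a `dvs_pull` table.
#' @export
compile_pull <- function(push_records, ref_grid) {
  keyed_from_push(push_records, ref_grid, layout = "pull")
}

#' Re-key push records by the overlap-ensemble base voxel (unified layout)
#'
#' Like [compile_pull()], but records are keyed by the minimum-index corner
#' ("voxel 1") of their 8-voxel overlap ensemble and store the three
#' quantized weight factors `w0` ([unified_weight_factors()]) instead of the
#' signed offsets. Because the factors are derived from the dequantized
#' offsets they are exact multiples of 1/127 in `[0, 1]`, so this second
#' quantization is lossless and the unified layout reproduces the push
#' layout's weights bit for bit.
#'
#' @inheritParams compile_pull
#' @return a `dvs_unified` table.
#' @export
compile_unified <- function(push_records, ref_grid) {
  keyed_from_push(push_records, ref_grid, layout = "unified")
}

keyed_from_push <- function(push, ref_grid, layout) {
  stopifnot(inherits(push, "dvs_push"))
  if (!all(push$ref_shape == ref_grid$shape))
    stop("reference grid does not match the compiled records")
  keep <- which(push$is_used != 0L)
  src <- keep - 1L                            # compile_push order = image flat order
  if (layout == "pull") {
    key <- push$target_index[keep]
    q <- push$dXb[keep, , drop = FALSE]
  } else {
    dXb <- push$dXb[keep, , drop = FALSE]
    nearest <- ijk_index(ref_grid, push$target_index[keep])
    base <- nearest + ifelse(dXb < 0L, -1, 0)
    key <- flat_index(ref_grid, base)
    w0 <- unified_weight_factors(dequantize_offset(dXb))$w0
    q <- matrix(quantize_offset(w0), ncol = 3L)
  }
  ord <- order(key, src)
  counts <- tabulate(key[ord] + 1L, nbins = n_voxels(ref_grid))
  new_dvs_keyed(layout,
                ranges = c(0L, cumsum(counts)),
                source_index = src[ord],
                image_shape = push$image_shape, ref_shape = push$ref_shape,
                dXb = if (layout == "pull") q[ord, , drop = FALSE],
                wb = if (layout == "unified") q[ord, , drop = FALSE])
}
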