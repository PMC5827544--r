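# File I/O: NIfTI scalar volumes, CSV traces and the binary .dvs container.
#
# All volumes are written with an axis-aligned qform (code 2) so that the
# affine encodes exactly origin + diag(spacing); oblique or sheared
# acquisitions are rejected on read. Values are stored as FLOAT64, making
# write -> read the identity at double precision.

#' Read a 3D scalar volume from NIfTI
#'
#' Accepts `.nii` / `.nii.gz` files with a 3D scalar payload and an
#' axis-aligned affine (no rotation or shear; positive spacings). The grid
#' geometry is taken from the file's affine: spacing from the diagonal,
#' origin from the translation column (position of voxel (0,0,0)).
#'
#' @param path path to a NIfTI file.
#' @param role role tag for the resulting [scalar_volume()] (default `"hu"`).
#' @return a [scalar_volume()].
#' @export
read_volume <- function(path, role = "hu") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("read_volume: expected a 3D payload, got %dD", length(d)))
  aff <- unclass(RNifti::xform(img))
  rot <- aff[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-6 * max(abs(diag(rot))) + 1e-9))
    stop("read_volume: only axis-aligned (non-sheared, non-rotated) affines are supported")
  spacing <- diag(rot)
  if (any(spacing <= 0))
    stop("read_volume: affine must have positive, axis-aligned spacing")
  vals <- as.vector(img)
  if (any(!is.finite(vals)))
    stop("read_volume: volume contains non-finite values")
  g <- grid3d(origin = aff[1:3, 4], spacing = spacing, shape = d)
  scalar_volume(g, vals, role = role)
}

#' Write a scalar volume to NIfTI
#'
#' The inverse of [read_volume()]: writes the values as FLOAT64 with an
#' axis-aligned qform so that reading the file back reproduces the volume
#' bit-for-bit at double precision.
#'
#' @param volume a [scalar_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "scalar_volume"))
  img <- RNifti::asNifti(as_array(volume))
  RNifti::pixdim(img) <- volume$grid$spacing
  aff <- rbind(cbind(diag(volume$grid$spacing), volume$grid$origin),
               c(0, 0, 0, 1))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read / write a target-position trace as CSV
#'
#' CSV with columns `time_s, x_mm, y_mm, z_mm`. Values are written with 17
#' significant digits so the round trip is the identity at double precision.
#'
#' @param path CSV path.
#' @param trace a [breathing_trace()].
#' @return `read_trace`: a [breathing_trace()]; `write_trace`: `path`,
#'   invisibly.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop(sprintf("read_trace: missing columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  breathing_trace(df$time_s, as.matrix(df[, c("x_mm", "y_mm", "z_mm")]))
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "breathing_trace"))
  out <- data.frame(lapply(unclass(trace)[c("time_s", "x_mm", "y_mm", "z_mm")],
                           function(col) sprintf("%.17g", col)))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- DVS binary container --------------------------------------------------
#
# Fixed 32-byte little-endian header:
#   bytes  0..3   magic "DVS1"
#   byte   4      format version (1)
#   byte   5      layout tag: 1 = push, 2 = pull, 3 = unified
#   bytes  6..7   reserved (0)
#   bytes  8..11  record count N (uint32)
#   bytes 12..17  moving image shape, 3 x uint16
#   bytes 18..23  reference grid shape, 3 x uint16
#   bytes 24..31  reserved (0)
# Push payload: N x 8-byte records (uint32 targetIndex, 3 x int8 quantized
# offsets, uint8 isUsed) -- file size is exactly 32 + 8 N.
# Pull/unified: a per-reference-voxel offset-index section (n_ref + 1 uint32
# cumulative record counts, part of the reference-grid bookkeeping) followed
# by N x 7-byte records (uint32 sourceIndex, 3 x int8 quantized offsets or
# weight factors); the per-displacement record payload is exactly 7 N bytes.

DVS_MAGIC <- charToRaw("DVS1")
DVS_HEADER_BYTES <- 32L
.layout_tags <- c(push = 1L, pull = 2L, unified = 3L)

raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
raw_i8 <- function(x) as.raw(bitwAnd(as.integer(x), 255L))

#' Write / read the binary DVS container
#'
#' Bit-exact little-endian serialization of a compiled DVS table
#' ([compile_push()], [compile_pull()], [compile_unified()]). Push records
#' occupy 8 bytes each (4-byte voxel index, three signed 1-byte quantized
#' offsets, status byte); pull and unified records occupy 7 bytes (no status
#' byte -- regions of interest live on the reference grid, so it is not
#' needed). Pull/unified files additionally carry the per-reference-voxel
#' record-range index. The round trip is the identity.
#'
#' @param table a DVS table from one of the compilers.
#' @param path output path (conventionally `.dvs`).
#' @return `write_dvs_container`: `path` invisibly; `read_dvs_container`:
#'   the table.
#' @export
write_dvs_container <- function(table, path) {
  stopifnot(inherits(table, "dvs_table"))
  layout <- table$layout
  n <- dvs_n_records(table)
  header <- c(DVS_MAGIC,
              as.raw(1L), as.raw(.layout_tags[[layout]]), as.raw(c(0L, 0L)),
              raw_u32(n),
              raw_u16(table$image_shape), raw_u16(table$ref_shape),
              raw(8L))
  stopifnot(length(header) == DVS_HEADER_BYTES)
  if (layout == "push") {
    rec <- matrix(raw(0L), nrow = 8L, ncol = n)
    rec[1:4, ] <- matrix(raw_u32(table$target_index), nrow = 4L)
    rec[5:7, ] <- matrix(raw_i8(t(table$dXb)), nrow = 3L)
    rec[8L, ] <- as.raw(table$is_used)
    payload <- as.vector(rec)
    index <- raw(0L)
  } else {
    q <- if (layout == "pull") table$dXb else table$wb
    rec <- matrix(raw(0L), nrow = 7L, ncol = n)
    if (n > 0L) {
      rec[1:4, ] <- matrix(raw_u32(table$source_index), nrow = 4L)
      rec[5:7, ] <- matrix(raw_i8(t(q)), nrow = 3L)
    }
    payload <- as.vector(rec)
    index <- raw_u32(table$ranges)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, index, payload), con)
  invisible(path)
}

#' @rdname write_dvs_container
#' @export
read_dvs_container <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < DVS_HEADER_BYTES)
    stop("read_dvs_container: file missing or shorter than the 32-byte header")
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, raw(), DVS_HEADER_BYTES)
  if (!identical(header[1:4], DVS_MAGIC))
    stop("read_dvs_container: bad magic; not a DVS container")
  if (as.integer(header[5]) != 1L)
    stop("read_dvs_container: unsupported format version")
  tag <- as.integer(header[6])
  layout <- names(.layout_tags)[match(tag, .layout_tags)]
  if (is.na(layout))
    stop(sprintf("read_dvs_container: unknown layout tag %d", tag))
  n <- readBin(header[9:12], integer(), size = 4L, endian = "little")
  image_shape <- readBin(header[13:18], integer(), n = 3L, size = 2L,
                         endian = "little", signed = FALSE)
  ref_shape <- readBin(header[19:24], integer(), n = 3L, size = 2L,
                       endian = "little", signed = FALSE)
  rec_bytes <- if (layout == "push") 8L else 7L
  n_ref <- prod(as.double(ref_shape))
  index_bytes <- if (layout == "push") 0 else 4 * (n_ref + 1)
  expect <- DVS_HEADER_BYTES + index_bytes + as.double(rec_bytes) * n
  if (sz != expect)
    stop(sprintf("read_dvs_container: size mismatch (have %d bytes, header implies %d)",
                 sz, expect))
  ranges <- NULL
  if (layout != "push")
    ranges <- readBin(con, integer(), n = n_ref + 1, size = 4L, endian = "little")
  payload <- readBin(con, raw(), rec_bytes * n)
  rec <- matrix(payload, nrow = rec_bytes)
  idx <- readBin(as.vector(rec[1:4, , drop = FALSE]), integer(), n = n,
                 size = 4L, endian = "little")
  q <- matrix(readBin(as.vector(rec[5:7, , drop = FALSE]), integer(),
                      n = 3L * n, size = 1L, signed = TRUE),
              nrow = 3L)
  if (layout == "push") {
    new_dvs_push(target_index = idx, dXb = t(q),
                 is_used = as.integer(rec[8L, ]),
                 image_shape = image_shape, ref_shape = ref_shape)
  } else if (layout == "pull") {
    new_dvs_keyed("pull", ranges = ranges, source_index = idx, dXb = t(q),
                  image_shape = image_shape, ref_shape = ref_shape)
  } else {
    new_dvs_keyed("unified", ranges = ranges, source_index = idx, wb = t(q),
                  image_shape = image_shape, ref_shape = ref_shape)
  }
}

dvs_n_records <- function(table) {
  if (table$layout == "push") length(table$target_index)
  else length(table$source_index)
}

new_dvs_push <- function(target_index, dXb, is_used, image_shape, ref_shape) {
  dXb <- matrix(as.integer(dXb), ncol = 3L)
  structure(list(layout = "push",
                 target_index = as.integer(target_index),
                 dXb = dXb,
                 is_used = as.integer(is_used),
                 image_shape = as.integer(image_shape),
                 ref_shape = as.integer(ref_shape)),
            class = c("dvs_push", "dvs_table"))
}

new_dvs_keyed <- function(layout, ranges, source_index, image_shape, ref_shape,
                          dXb = NULL, wb = NULL) {
  out <- list(layout = layout,
              ranges = as.integer(ranges),
              source_index = as.integer(source_index),
              image_shape = as.integer(image_shape),
              ref_shape = as.integer(ref_shape))
  if (layout == "pull") out$dXb <- matrix(as.integer(dXb), ncol = 3L)
  else out$wb <- matrix(as.integer(wb), ncol = 3L)
  structure(out, class = c(paste0("dvs_", layout), "dvs_table"))
}

#' @export
print.dvs_table <- function(x, ...) {
  n <- dvs_n_records(x)
  cat(sprintf("DVS table, %s layout: %d records (%d bytes each)\n",
              x$layout, n, if (x$layout == "push") 8L else 7L))
  cat(sprintf("  image grid %s -> reference grid %s\n",
              paste(x$image_shape, collapse = "x"),
              paste(x$ref_shape, collapse = "x")))
  if (x$layout == "push")
    cat(sprintf("  used records: %d\n", sum(x$is_used != 0L)))
  invisible(x)
}
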