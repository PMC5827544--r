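# HU -> density -> per-image-voxel mass, and the relation between the fine
# image grid and the coarser dose/energy grid (integer voxel ratio).

#' Convert a HU image to mass density
#'
#' Default calibration is the linear water ramp \eqn{\rho = 1 + HU/1000}
#' clamped at zero (air at -1000 HU, water at 0 HU), in g/cm^3. The mapping
#' method itself is agnostic to the calibration, so any monotone
#' user-supplied conversion can be plugged in via `calibration`.
#'
#' @param hu_volume a [scalar_volume()] with role `"hu"`.
#' @param calibration optional function HU -> density (g/cm^3); must return
#'   non-negative finite values.
#' @return a [scalar_volume()] with role `"density"`.
#' @examples
#' g <- grid3d(shape = c(2, 2, 1))
#' hu <- scalar_volume(g, c(0, -1000, -1500, 55), role = "hu")
#' hu_to_density(hu)$values  # 1.0, 0.0, 0.0 (clamped), 1.055
#' @export
hu_to_density <- function(hu_volume, calibration = NULL) {
  stopifnot(inherits(hu_volume, "scalar_volume"))
  if (hu_volume$role != "hu")
    stop("hu_to_density: input role must be 'hu'")
  f <- if (is.null(calibration)) function(hu) pmax(0, 1 + hu / 1000) else calibration
  rho <- f(hu_volume$values)
  scalar_volume(hu_volume$grid, rho, role = "density")
}

#' Per-image-voxel mass
#'
#' Mass of each image voxel: \eqn{m = \rho V_A} with \eqn{V_A} the image
#' voxel volume (spacings in mm converted to cm^3), in grams.
#'
#' @param density_volume a [scalar_volume()] with role `"density"` (g/cm^3).
#' @return a [scalar_volume()] with role `"mass"` (g).
#' @export
image_voxel_mass <- function(density_volume) {
  stopifnot(inherits(density_volume, "scalar_volume"))
  if (density_volume$role != "density")
    stop("image_voxel_mass: input role must be 'density'")
  v_a <- prod(density_volume$grid$spacing) / 1000  # mm^3 -> cm^3
  scalar_volume(density_volume$grid, density_volume$values * v_a, role = "mass")
}

#' Relate the fine image grid to the coarse dose/energy grid
#'
#' Image and dose grids are rectilinear and mutually aligned with an integer
#' voxel ratio per axis (clinically 2 x 2 x 1 image voxels per dose voxel for
#' 1 x 1 x 2 mm images and 2 x 2 x 2 mm dose). The image voxel block
#' `(0..ratio-1)^3` lies inside dose voxel 0, i.e. dose spacing =
#' image spacing * ratio and both volumes cover the same physical box.
#'
#' @param image_grid,dose_grid [grid3d()] objects.
#' @return an object of class `grid_alignment` with the integer `ratio`.
#' @export
grid_alignment <- function(image_grid, dose_grid) {
  stopifnot(inherits(image_grid, "grid3d"), inherits(dose_grid, "grid3d"))
  ratio <- dose_grid$spacing / image_grid$spacing
  ratio_i <- as.integer(round(ratio))
  if (any(ratio_i < 1L) ||
      any(abs(ratio - ratio_i) > 1e-9 * pmax(1, abs(ratio))))
    stop("grid_alignment: dose spacing must be an exact integer multiple of image spacing")
  if (!all(image_grid$shape == dose_grid$shape * ratio_i))
    stop("grid_alignment: image shape must equal dose shape * ratio")
  # shared origin convention: centre of image voxel 0 sits inside dose voxel 0
  # when corner-aligned: dose origin = image origin + (ratio - 1)/2 * image spacing
  expect_origin <- image_grid$origin + (ratio_i - 1) / 2 * image_grid$spacing
  if (any(abs(dose_grid$origin - expect_origin) >
          1e-6 * pmax(1, abs(expect_origin))))
    stop("grid_alignment: grids are not corner-aligned (dose voxel 0 must contain image block 0)")
  structure(list(image_grid = image_grid, dose_grid = dose_grid,
                 ratio = ratio_i),
            class = "grid_alignment")
}

#' @export
print.grid_alignment <- function(x, ...) {
  cat(sprintf("grid_alignment: %s image voxels per dose voxel\n",
              paste(x$ratio, collapse = " x ")))
  invisible(x)
}

#' Dose voxel containing an image voxel
#'
#' The dose value sampled for an image voxel is the (piecewise-constant)
#' dose of its containing coarse voxel: `dose_index = floor(image_index /
#' ratio)` per axis; no interpolation.
#'
#' @param image_index 0-based ijk index (length-3 vector or n x 3 matrix).
#' @param alignment a [grid_alignment()].
#' @return 0-based dose-grid ijk indices, same shape as the input.
#' @export
containing_dose_voxel <- function(image_index, alignment) {
  stopifnot(inherits(alignment, "grid_alignment"))
  m <- rbind2mat(image_index)
  if (any(m < 0) || any(sweep(m, 2, alignment$image_grid$shape, `>=`)))
    stop("containing_dose_voxel: image index out of range")
  out <- sweep(m, 2, as.numeric(alignment$ratio), `%/%`)
  if (is.matrix(image_index)) out else as.vector(out)
}

# Flat map image voxel -> flat index of its containing dose voxel,
# for all image voxels in flat order.
image_to_dose_map <- function(alignment) {
  ig <- alignment$image_grid
  ijk <- ijk_index(ig, seq_len(n_voxels(ig)) - 1)
  dose_ijk <- sweep(ijk, 2, as.numeric(alignment$ratio), `%/%`)
  flat_index(alignment$dose_grid, dose_ijk)
}
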