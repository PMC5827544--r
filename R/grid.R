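#' Rectilinear 3D voxel lattice
#'
#' Defines the geometry shared by images, dose cubes, displacement fields and
#' accumulator volumes: a physical origin (mm), a per-axis voxel spacing
#' \eqn{r_i} (mm) and integer voxel counts. The centre of voxel `(0,0,0)` sits
#' at `origin`; the centre of 0-based voxel index `v` is
#' `origin + v * spacing` (elementwise). Flat (linear) indices are 0-based
#' with axis 1 fastest: `flat = v1 + shape1 * (v2 + shape2 * v3)`, which is
#' also the memory order of the `values` vector of a [scalar_volume()].
#'
#' @param origin numeric length-3, mm; position of the centre of voxel (0,0,0).
#' @param spacing numeric length-3, mm per voxel, strictly positive.
#' @param shape integer length-3, voxel counts per axis, strictly positive.
#' @return an object of class `grid3d`.
#' @examples
#' g <- grid3d(origin = c(0, 0, 0), spacing = c(1, 1, 2), shape = c(64, 64, 40))
#' voxel_centre(g, c(1, 0, 0))  # (1, 0, 0) mm
#' @export
grid3d <- function(origin = c(0, 0, 0), spacing = c(1, 1, 1), shape) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(shape) == 3L)
  if (any(!is.finite(origin)) || any(!is.finite(spacing)))
    stop("grid3d: origin and spacing must be finite")
  if (any(spacing <= 0)) stop("grid3d: spacing must be strictly positive")
  if (any(shape < 1L)) stop("grid3d: shape must be positive")
  structure(list(origin = origin, spacing = spacing, shape = shape),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("grid3d: %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

n_voxels <- function(grid) prod(as.double(grid$shape))

grids_equal <- function(a, b, tol = 1e-9) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol * pmax(1, abs(a$spacing))) &&
    all(abs(a$origin - b$origin) <= tol * pmax(1, abs(a$origin)))
}

#' Convert between voxel indices and physical coordinates
#'
#' `voxel_centre` maps 0-based ijk indices (rows of a matrix, or a length-3
#' vector) to physical mm coordinates; `flat_index` and `ijk_index` convert
#' between 0-based ijk triples and 0-based flat indices (axis 1 fastest).
#'
#' @param grid a [grid3d()].
#' @param ijk integer matrix (n x 3) or length-3 vector of 0-based indices.
#' @param flat numeric/integer vector of 0-based flat indices.
#' @return `voxel_centre`: n x 3 matrix of mm coordinates; `flat_index`:
#'   0-based flat indices; `ijk_index`: n x 3 matrix of 0-based ijk.
#' @export
voxel_centre <- function(grid, ijk) {
  ijk <- rbind2mat(ijk)
  sweep(sweep(ijk, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

#' @rdname voxel_centre
#' @export
flat_index <- function(grid, ijk) {
  ijk <- rbind2mat(ijk)
  s <- grid$shape
  if (any(ijk < 0) || any(sweep(ijk, 2, s, `>=`)))
    stop("flat_index: index out of range")
  ijk[, 1] + s[1] * (ijk[, 2] + s[2] * ijk[, 3])
}

#' @rdname voxel_centre
#' @export
ijk_index <- function(grid, flat) {
  s <- grid$shape
  flat <- as.double(flat)
  if (any(flat < 0) || any(flat >= n_voxels(grid)))
    stop("ijk_index: flat index out of range")
  i <- flat %% s[1]
  j <- (flat %/% s[1]) %% s[2]
  k <- flat %/% (as.double(s[1]) * s[2])
  cbind(i, j, k, deparse.level = 0)
}

rbind2mat <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1)
}

volume_roles <- c("hu", "density", "dose", "energy", "mass")

#' One scalar value per voxel on a grid
#'
#' The workhorse container: a [grid3d()] plus a values vector in flat-index
#' order (axis 1 fastest, identical to R's column-major array layout) and a
#' role tag. Roles `density`, `energy` and `mass` must be non-negative
#' everywhere; all roles must be finite.
#'
#' @param grid a [grid3d()].
#' @param values numeric vector of length `prod(shape)` (flat order) or a 3D
#'   array of matching dim.
#' @param role one of `"hu"`, `"density"`, `"dose"`, `"energy"`, `"mass"`.
#' @return an object of class `scalar_volume`.
#' @seealso [as_array.scalar_volume()]
#' @export
scalar_volume <- function(grid, values, role = c("hu", "density", "dose",
                                                 "energy", "mass")) {
  role <- match.arg(role)
  stopifnot(inherits(grid, "grid3d"))
  if (is.array(values)) {
    if (length(dim(values)) != 3L || !all(dim(values) == grid$shape))
      stop("scalar_volume: array dim does not match grid shape")
    values <- as.vector(values)
  }
  values <- as.numeric(values)
  if (length(values) != n_voxels(grid))
    stop("scalar_volume: value count does not equal the voxel count")
  if (any(!is.finite(values)))
    stop("scalar_volume: values must be finite")
  if (role %in% c("density", "energy", "mass") && any(values < 0))
    stop(sprintf("scalar_volume: role '%s' must be non-negative", role))
  if (role == "dose" && any(values < 0))
    stop("scalar_volume: dose must be non-negative")
  structure(list(grid = grid, values = values, role = role),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("scalar_volume [%s]: ", x$role))
  print(x$grid)
  cat(sprintf("  values in [%g, %g], sum %g\n",
              min(x$values), max(x$values), sum(x$values)))
  invisible(x)
}

#' @export
as_array <- function(x, ...) UseMethod("as_array")

#' View a scalar volume as a 3D array
#'
#' @param x a [scalar_volume()].
#' @param ... unused.
#' @return a 3D numeric array (flat order equals R column-major order).
#' @export
as_array.scalar_volume <- function(x, ...) {
  array(x$values, dim = x$grid$shape)
}

#' Per-image-voxel displacement vectors (moving phase to reference space)
#'
#' One 3-vector (mm) per voxel of the moving image grid, mapping that voxel's
#' centre to a point in reference space. This is the forward direction
#' consumed by [compile_push()].
#'
#' @param grid the moving image [grid3d()].
#' @param vectors numeric n x 3 matrix (n = voxel count, flat order), mm.
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(grid, vectors) {
  stopifnot(inherits(grid, "grid3d"))
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 3L || nrow(vectors) != n_voxels(grid))
    stop("displacement_field: need one 3-vector per image voxel")
  if (any(!is.finite(vectors)))
    stop("displacement_field: vector components must be finite")
  storage.mode(vectors) <- "double"
  dimnames(vectors) <- NULL
  structure(list(grid = grid, vectors = vectors),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat("displacement_field on "); print(x$grid)
  mag <- sqrt(rowSums(x$vectors^2))
  cat(sprintf("  |v| in [%g, %g] mm\n", min(mag), max(mag)))
  invisible(x)
}

#' Target-position trace over time
#'
#' Timestamps (s, strictly increasing) with 3D target positions (mm); drives
#' respiratory-phase selection in the reconstruction loop. Traces generated
#' by the phantom are uniformly sampled at the 40 ms machine-log tick.
#'
#' @param time_s numeric vector, strictly increasing, seconds.
#' @param positions numeric n x 3 matrix, mm.
#' @return an object of class `breathing_trace` (also a data.frame with
#'   columns `time_s`, `x_mm`, `y_mm`, `z_mm`).
#' @export
breathing_trace <- function(time_s, positions) {
  time_s <- as.numeric(time_s)
  positions <- as.matrix(positions)
  if (length(time_s) < 1L) stop("breathing_trace: need at least one sample")
  if (nrow(positions) != length(time_s) || ncol(positions) != 3L)
    stop("breathing_trace: positions must be an n x 3 matrix")
  if (any(diff(time_s) <= 0))
    stop("breathing_trace: timestamps must be strictly increasing")
  if (any(!is.finite(time_s)) || any(!is.finite(positions)))
    stop("breathing_trace: non-finite values")
  out <- data.frame(time_s = time_s, x_mm = positions[, 1],
                    y_mm = positions[, 2], z_mm = positions[, 3])
  class(out) <- c("breathing_trace", "data.frame")
  out
}

trace_positions <- function(trace) {
  unname(as.matrix(trace[, c("x_mm", "y_mm", "z_mm")]))
}
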