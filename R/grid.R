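#' Physical image grid
#'
#' A 3D voxel lattice embedded in physical space. Voxel index `i` (0-based)
#' maps to the physical coordinate `origin + i * spacing`, axis-wise, in mm.
#' All volumes, displacement fields and attention maps in this package carry
#' an `image_grid` and operations between objects require matching grids.
#'
#' @param shape integer vector of length 3, voxel counts per axis (> 0).
#' @param spacing numeric vector of length 3, voxel size in mm (> 0).
#' @param origin numeric vector of length 3, physical position of voxel
#'   (0,0,0) in mm.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be 3 positive integers")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive reals (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite reals (mm)")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %s voxels, spacing %s mm, origin %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Voxel volume of a grid
#' @param grid an [image_grid()].
#' @return scalar, mm^3 per voxel.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Compare two grids
#' @param a,b [image_grid()] objects.
#' @param tol absolute tolerance on spacing and origin, mm.
#' @return logical.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch: %s must share one grid", what))
}

#' Physical coordinates of all voxels
#'
#' @param grid an [image_grid()].
#' @return a list of three 3D arrays (x, y, z physical coordinates in mm).
#' @export
grid_coordinates <- function(grid) {
  s <- grid$shape
  ax <- lapply(1:3, function(k) grid$origin[k] + (seq_len(s[k]) - 1) * grid$spacing[k])
  list(x = array(rep(ax[[1]], times = s[2] * s[3]), dim = s),
       y = array(rep(rep(ax[[2]], each = s[1]), times = s[3]), dim = s),
       z = array(rep(ax[[3]], each = s[1] * s[2]), dim = s))
}

#' Scalar volume on a physical grid
#'
#' @param values 3D numeric array matching `grid$shape`; all values finite.
#' @param grid an [image_grid()].
#' @return An object of class `scalar_volume` with fields `values`, `grid`.
#' @export
scalar_volume <- function(values, grid) {
  if (length(dim(values)) != 3L || !all(dim(values) == grid$shape))
    stop("'values' must be a 3D array matching grid$shape")
  if (!all(is.finite(values))) stop("scalar_volume values must be finite")
  structure(list(values = values, grid = grid), class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("scalar_volume\n  "); print(x$grid)
  cat(sprintf("  intensity range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Dense displacement field (fixed -> moving)
#'
#' Stores `u(x)` in physical mm on the fixed image's grid; the deformation is
#' `Phi(x) = x + u(x)` mapping fixed-image physical coordinates to
#' moving-image physical coordinates.
#'
#' @param vectors 4D numeric array `c(grid$shape, 3)`, mm; all finite.
#' @param grid the fixed image's [image_grid()].
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, grid) {
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L || !all(d[1:3] == grid$shape))
    stop("'vectors' must be a 4D array c(grid$shape, 3)")
  if (!all(is.finite(vectors))) stop("displacement_field vectors must be finite")
  structure(list(vectors = vectors, grid = grid), class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat("displacement_field (fixed -> moving)\n  "); print(x$grid)
  cat(sprintf("  max |u| = %.3f mm\n",
              sqrt(max(rowSums(matrix(x$vectors, ncol = 3)^2)))))
  invisible(x)
}

#' Zero displacement field on a grid
#' @param grid an [image_grid()].
#' @return a [displacement_field()] with all components zero.
#' @export
zero_field <- function(grid) {
  displacement_field(array(0, c(grid$shape, 3L)), grid)
}

#' Attention maps (shrinkage / expansion / background)
#'
#' Per-voxel channel weights produced by the temperature SoftMax of the
#' attention network; channels sum to one at every voxel and are near-binary
#' for large temperatures.
#'
#' @param channels 4D array `c(grid$shape, 3)` with channel order
#'   (shrink, expand, background); each value in `[0, 1]`.
#' @param grid an [image_grid()].
#' @param check validate the per-voxel sum-to-one invariant (default TRUE).
#' @return An object of class `attention_maps`.
#' @export
attention_maps <- function(channels, grid, check = TRUE) {
  d <- dim(channels)
  if (length(d) != 4L || d[4] != 3L || !all(d[1:3] == grid$shape))
    stop("'channels' must be a 4D array c(grid$shape, 3)")
  if (check) {
    if (min(channels) < -1e-8 || max(channels) > 1 + 1e-8)
      stop("attention channels must lie in [0, 1]")
    s <- channels[, , , 1] + channels[, , , 2] + channels[, , , 3]
    if (max(abs(s - 1)) > 1e-5)
      stop("attention channels must sum to 1 per voxel (tol 1e-5)")
  }
  structure(list(channels = channels, grid = grid), class = "attention_maps")
}

#' Extract one attention channel
#' @param att an [attention_maps()] object.
#' @param channel one of "shrink", "expand", "background".
#' @return a 3D array of per-voxel weights.
#' @export
attention_channel <- function(att, channel = c("shrink", "expand", "background")) {
  channel <- match.arg(channel)
  att$channels[, , , match(channel, c("shrink", "expand", "background"))]
}

#' Jacobian determinant map
#'
#' @param det 3D numeric array of `det(grad Phi)` values (dimensionless).
#' @param grid an [image_grid()].
#' @return An object of class `jacobian_map`.
#' @export
jacobian_map <- function(det, grid) {
  if (length(dim(det)) != 3L || !all(dim(det) == grid$shape))
    stop("'det' must be a 3D array matching grid$shape")
  if (!all(is.finite(det))) stop("jacobian_map values must be finite")
  structure(list(det = det, grid = grid), class = "jacobian_map")
}
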