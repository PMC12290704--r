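# Finite-difference derivative of a 3D array along one axis, in physical
# units: central differences in the interior, one-sided at the two border
# slices. Needs >= 3 slices along the axis.
axis_gradient <- function(a, spacing, axis) {
  d <- dim(a)
  n <- d[axis]
  if (n < 3L) stop("degenerate grid: need at least 3 voxels per axis")
  take <- function(i) {
    ix <- lapply(d, seq_len)
    ix[[axis]] <- i
    do.call(`[`, c(list(a), ix, list(drop = FALSE)))
  }
  put <- function(arr, i, value) {
    ix <- lapply(d, seq_len)
    ix[[axis]] <- i
    do.call(`[<-`, c(list(arr), ix, list(value)))
  }
  g <- array(0, d)
  g <- put(g, 2:(n - 1), (take(3:n) - take(1:(n - 2))) / (2 * spacing))
  g <- put(g, 1L, (take(2L) - take(1L)) / spacing)
  g <- put(g, n, (take(n) - take(n - 1L)) / spacing)
  g
}

#' Jacobian determinant of a deformation
#'
#' For the deformation `Phi(x) = x + u(x)` the per-voxel determinant of
#' `grad Phi = I + grad u` is computed with spacing-scaled central
#' differences (one-sided at the borders). A zero field yields 1 everywhere;
#' values below 1 indicate local contraction, above 1 local expansion.
#'
#' @param field a [displacement_field()].
#' @return a [jacobian_map()].
#' @export
jacobian_determinant <- function(field) {
  g <- field$grid
  if (any(g$shape < 3L)) stop("degenerate grid: every axis must have >= 3 voxels")
  J <- vector("list", 9L)  # J[[3*(j-1)+i]] = d(Phi_i)/d(x_j)
  for (i in 1:3) {
    ui <- field$vectors[, , , i]
    for (j in 1:3) {
      d <- axis_gradient(ui, g$spacing[j], j)
      if (i == j) d <- d + 1
      J[[3L * (j - 1L) + i]] <- d
    }
  }
  det <- J[[1]] * (J[[5]] * J[[9]] - J[[8]] * J[[6]]) -
         J[[4]] * (J[[2]] * J[[9]] - J[[8]] * J[[3]]) +
         J[[7]] * (J[[2]] * J[[6]] - J[[5]] * J[[3]])
  jacobian_map(array(det, dim = g$shape), g)
}

#' Region volumes in fixed and moving image space
#'
#' Integrates a per-voxel region weight (an attention channel or a binary
#' mask) over the fixed image, and over its image under the deformation:
#' `v_fixed = sum(s * dV)` and `v_moving = sum(s * |det grad Phi| * dV)`
#' (change of variables; identical to integrating the mapped region for a
#' diffeomorphic field, with the absolute value guarding rare negative
#' determinants in noisy fields).
#'
#' @param weights a 3D array of per-voxel weights in `[0, 1]`, a
#'   [scalar_volume()], or an [attention_maps()] object (then `channel`
#'   selects the map).
#' @param field a [displacement_field()] on the same grid.
#' @param channel attention channel when `weights` is an [attention_maps()].
#' @param jacobian optional precomputed [jacobian_map()] for `field` (saves
#'   recomputation in inner loops).
#' @return named numeric vector `c(v_fixed =, v_moving =)`, mm^3.
#' @export
region_volumes <- function(weights, field, channel = "shrink", jacobian = NULL) {
  if (inherits(weights, "attention_maps")) {
    stop_if_grid_mismatch(weights$grid, field$grid, "attention maps and field")
    w <- attention_channel(weights, channel)
  } else if (inherits(weights, "scalar_volume")) {
    stop_if_grid_mismatch(weights$grid, field$grid, "weights and field")
    w <- weights$values
  } else {
    if (!all(dim(weights) == field$grid$shape))
      stop("grid mismatch: weights array does not match the field grid")
    w <- weights
  }
  if (is.null(jacobian)) jacobian <- jacobian_determinant(field)
  else stop_if_grid_mismatch(jacobian$grid, field$grid, "jacobian and field")
  dv <- voxel_volume(field$grid)
  c(v_fixed = sum(w) * dv,
    v_moving = sum(w * abs(jacobian$det)) * dv)
}
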