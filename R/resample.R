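# Trilinear resampling helpers shared by augmentation, heatmap aggregation
# and the phantom confound warp.

# Sample a 3D array (on `grid`) at arbitrary physical points (n x 3 matrix).
# Returns list(values, inside); points outside the grid give 0 / inside = 0.
sample_volume_at <- function(values, grid, points) {
  res <- .sample_trilinear(as.numeric(values),
                           grid$shape[1], grid$shape[2], grid$shape[3],
                           as.numeric(grid$spacing), as.numeric(grid$origin),
                           points)
  list(values = as.numeric(res$values), inside = as.numeric(res$inside))
}

#' Warp a volume through a displacement field
#'
#' Pull-back resampling: the output on `field$grid` takes the value of `vol`
#' at `x + u(x)`. Used to bring attention maps into a template space and to
#' apply synthetic confound warps.
#'
#' @param vol a [scalar_volume()] (or 3D array on `field$grid`).
#' @param field a [displacement_field()] whose grid defines the output.
#' @param fill value for points mapped outside `vol`'s grid.
#' @return list with `volume` (a [scalar_volume()] on `field$grid`) and
#'   `inside` (3D 0/1 array marking in-domain samples).
#' @export
warp_volume <- function(vol, field, fill = 0) {
  src_values <- if (inherits(vol, "scalar_volume")) vol$values else vol
  src_grid <- if (inherits(vol, "scalar_volume")) vol$grid else field$grid
  co <- grid_coordinates(field$grid)
  pts <- cbind(as.numeric(co$x) + as.numeric(field$vectors[, , , 1]),
               as.numeric(co$y) + as.numeric(field$vectors[, , , 2]),
               as.numeric(co$z) + as.numeric(field$vectors[, , , 3]))
  res <- sample_volume_at(src_values, src_grid, pts)
  v <- res$values
  if (fill != 0) v[res$inside == 0] <- fill
  list(volume = scalar_volume(array(v, dim = field$grid$shape), field$grid),
       inside = array(res$inside, dim = field$grid$shape))
}
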