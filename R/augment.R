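# Training-time augmentation. The same spatial transform is applied to the
# fixed image, the moving image and the displacement field of a pair
# (vector components are co-rotated / reflected), so the deformation-induced
# volume change of any co-transformed region is preserved. Order labels and
# interval ratios are metadata and never touched.

#' Augmentation configuration
#'
#' @param normalize z-score each volume (always recommended; the network is
#'   trained on normalized intensities).
#' @param rot_max_deg maximum rotation magnitude (degrees) about a random
#'   coordinate axis; 0 disables rotation.
#' @param crop_shape integer extent of the random crop (3 values or 1
#'   recycled), or NULL for no crop. Must be compatible with the network
#'   depth (divisible by `2^(depth-1)`).
#' @param crop_center voxel (1-based) around which crops are centered;
#'   default the volume center.
#' @param crop_jitter maximum per-axis crop offset in voxels.
#' @param flip randomly reflect each axis with probability 1/2.
#' @param erase_prob probability of erasing a random rectangular patch from
#'   both images (intensity set to 0 post-normalization).
#' @param erase_frac range of the patch size as a fraction of each extent.
#' @return list of class `augment_config`.
#' @export
augment_config <- function(normalize = TRUE, rot_max_deg = 8,
                           crop_shape = NULL, crop_center = NULL,
                           crop_jitter = 2, flip = TRUE,
                           erase_prob = 0, erase_frac = c(0.1, 0.25)) {
  structure(list(normalize = normalize, rot_max_deg = rot_max_deg,
                 crop_shape = crop_shape, crop_center = crop_center,
                 crop_jitter = crop_jitter, flip = flip,
                 erase_prob = erase_prob, erase_frac = erase_frac),
            class = "augment_config")
}

rotation_matrix <- function(axis, theta) {
  c1 <- cos(theta); s1 <- sin(theta)
  R <- diag(3)
  ij <- switch(axis, `1` = c(2, 3), `2` = c(1, 3), `3` = c(1, 2))
  R[ij[1], ij[1]] <- c1; R[ij[2], ij[2]] <- c1
  R[ij[1], ij[2]] <- -s1; R[ij[2], ij[1]] <- s1
  R
}

rotate_pair_arrays <- function(pair, R) {
  grid <- pair$fixed$grid
  ctr <- grid$origin + (grid$shape - 1) / 2 * grid$spacing
  co <- grid_coordinates(grid)
  pts <- cbind(as.numeric(co$x) - ctr[1], as.numeric(co$y) - ctr[2],
               as.numeric(co$z) - ctr[3])
  src <- pts %*% R  # R^T (x - c), pull-back of the rotation
  src <- sweep(src, 2, ctr, "+")
  resample <- function(values, fill) {
    r <- sample_volume_at(values, grid, src)
    v <- r$values
    v[r$inside == 0] <- fill
    array(v, grid$shape)
  }
  fx <- resample(pair$fixed$values, stats::median(pair$fixed$values))
  mv <- resample(pair$moving$values, stats::median(pair$moving$values))
  u <- vapply(1:3, function(k) resample(pair$field$vectors[, , , k], 0),
              array(0, grid$shape))
  urot <- array(0, c(grid$shape, 3L))
  um <- matrix(u, ncol = 3)
  um <- um %*% t(R)  # rotate sampled vectors into the new frame
  for (k in 1:3) urot[, , , k] <- array(um[, k], grid$shape)
  pair$fixed <- scalar_volume(fx, grid)
  pair$moving <- scalar_volume(mv, grid)
  pair$field <- displacement_field(urot, grid)
  pair
}

crop_pair <- function(pair, shape, center, jitter) {
  grid <- pair$fixed$grid
  shape <- as.integer(rep(shape, length.out = 3))
  if (any(shape > grid$shape)) stop("crop larger than volume")
  if (is.null(center)) center <- (grid$shape + 1) / 2
  off <- if (jitter > 0) sample(seq(-jitter, jitter), 3, replace = TRUE) else c(0, 0, 0)
  start <- as.integer(round(center - shape / 2 + off))
  start <- pmin(pmax(start, 1L), grid$shape - shape + 1L)
  ix <- lapply(1:3, function(k) start[k]:(start[k] + shape[k] - 1L))
  ngrid <- image_grid(shape, grid$spacing,
                      grid$origin + (start - 1L) * grid$spacing)
  sub3 <- function(a) a[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  pair$fixed <- scalar_volume(sub3(pair$fixed$values), ngrid)
  pair$moving <- scalar_volume(sub3(pair$moving$values), ngrid)
  pair$field <- displacement_field(
    pair$field$vectors[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE], ngrid)
  pair
}

flip_pair <- function(pair, axes) {
  if (!any(axes)) return(pair)
  grid <- pair$fixed$grid
  ix <- lapply(1:3, function(k) if (axes[k]) rev(seq_len(grid$shape[k]))
                                else seq_len(grid$shape[k]))
  f3 <- function(a) a[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  pair$fixed <- scalar_volume(f3(pair$fixed$values), grid)
  pair$moving <- scalar_volume(f3(pair$moving$values), grid)
  u <- pair$field$vectors[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
  for (k in 1:3) if (axes[k]) u[, , , k] <- -u[, , , k]
  pair$field <- displacement_field(u, grid)
  pair
}

erase_patch <- function(pair, frac) {
  d <- pair$fixed$grid$shape
  side <- pmax(1L, as.integer(round(stats::runif(3, frac[1], frac[2]) * d)))
  start <- vapply(1:3, function(k) sample.int(d[k] - side[k] + 1L, 1), 1L)
  ix <- lapply(1:3, function(k) start[k]:(start[k] + side[k] - 1L))
  pair$fixed$values[ix[[1]], ix[[2]], ix[[3]]] <- 0
  pair$moving$values[ix[[1]], ix[[2]], ix[[3]]] <- 0
  pair
}

#' Augment a scan pair
#'
#' Applies intensity normalization and the configured random spatial
#' transforms, identically to the fixed image, moving image and
#' displacement field. Deterministic given `seed`. With all augmentations
#' disabled this reduces to intensity normalization only.
#'
#' @param pair a `pair_sample` (see [cohort_pair()]).
#' @param config an [augment_config()].
#' @param seed integer seed.
#' @return the transformed `pair_sample`.
#' @export
augment_pair <- function(pair, config = augment_config(), seed = 1L) {
  local_seed(seed, {
    if (config$normalize) {
      pair$fixed <- zscore_volume(pair$fixed)
      pair$moving <- zscore_volume(pair$moving)
    }
    if (config$rot_max_deg > 0) {
      theta <- stats::runif(1, -config$rot_max_deg, config$rot_max_deg) * pi / 180
      axis <- sample.int(3, 1)
      pair <- rotate_pair_arrays(pair, rotation_matrix(axis, theta))
    }
    if (!is.null(config$crop_shape))
      pair <- crop_pair(pair, config$crop_shape, config$crop_center,
                        config$crop_jitter)
    if (config$flip)
      pair <- flip_pair(pair, stats::runif(3) < 0.5)
    if (config$erase_prob > 0 && stats::runif(1) < config$erase_prob)
      pair <- erase_patch(pair, config$erase_frac)
    pair
  })
}
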