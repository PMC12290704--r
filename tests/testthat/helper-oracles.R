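# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own computation paths (grid Jacobians, cone formulas, ranking
# code) so they can arbitrate correctness.

tiny_grid <- function(n = 16, spacing = c(1, 1, 1)) {
  image_grid(rep(n, 3), spacing)
}

# uniform linear scaling u(x) = (s - 1) (x - c)
uniform_scale_field <- function(grid, s, ctr = NULL) {
  if (is.null(ctr)) ctr <- grid$origin + (grid$shape - 1) / 2 * grid$spacing
  co <- rdatrophy:::grid_coordinates(grid)
  u <- array(0, c(grid$shape, 3))
  u[, , , 1] <- (s - 1) * (co$x - ctr[1])
  u[, , , 2] <- (s - 1) * (co$y - ctr[2])
  u[, , , 3] <- (s - 1) * (co$z - ctr[3])
  displacement_field(u, grid)
}

ball_mask <- function(grid, radius, ctr = NULL) {
  if (is.null(ctr)) ctr <- grid$origin + (grid$shape - 1) / 2 * grid$spacing
  co <- rdatrophy:::grid_coordinates(grid)
  q <- sqrt((co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2)
  array(as.numeric(q <= radius), grid$shape)
}

# closure-based smooth field (sum of Gaussian bumps) that can be evaluated
# at arbitrary points, for refined-grid oracles
bump_field_spec <- function(grid, n_bumps = 3, amplitude = 1.5, seed = 1) {
  lo <- grid$origin
  hi <- grid$origin + (grid$shape - 1) * grid$spacing
  rdatrophy:::local_seed(seed, {
    list(centers = matrix(runif(3 * n_bumps, lo, hi), ncol = 3, byrow = TRUE),
         amps = matrix(rnorm(3 * n_bumps, sd = amplitude / sqrt(n_bumps)),
                       ncol = 3),
         sigma = mean(hi - lo) / 4)
  })
}

bump_field_eval <- function(spec, pts) {
  u <- matrix(0, nrow(pts), 3)
  for (b in seq_len(nrow(spec$centers))) {
    d2 <- (pts[, 1] - spec$centers[b, 1])^2 +
          (pts[, 2] - spec$centers[b, 2])^2 +
          (pts[, 3] - spec$centers[b, 3])^2
    g <- exp(-d2 / (2 * spec$sigma^2))
    u <- u + outer(g, spec$amps[b, ])
  }
  u
}

bump_field_on_grid <- function(spec, grid) {
  co <- rdatrophy:::grid_coordinates(grid)
  pts <- cbind(as.numeric(co$x), as.numeric(co$y), as.numeric(co$z))
  u <- bump_field_eval(spec, pts)
  arr <- array(0, c(grid$shape, 3))
  for (k in 1:3) arr[, , , k] <- array(u[, k], grid$shape)
  displacement_field(arr, grid)
}

# analytic-step central-difference Jacobian determinant at given physical
# points (independent of the package's grid stencil)
bump_field_detj <- function(spec, pts, h) {
  n <- nrow(pts)
  J <- array(0, c(n, 3, 3))
  for (j in 1:3) {
    dp <- pts; dm <- pts
    dp[, j] <- dp[, j] + h
    dm[, j] <- dm[, j] - h
    dU <- (bump_field_eval(spec, dp) - bump_field_eval(spec, dm)) / (2 * h)
    for (i in 1:3) J[, i, j] <- dU[, i] + as.numeric(i == j)
  }
  J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
    J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
    J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
}

# Monte-Carlo point-mapping volume oracle: the volume of the image of the
# mask region under Phi, estimated by uniform sampling of a bounding box in
# moving space with membership tested through fixed-point inversion of
# Phi(x) = x + u(x) (u interpolated trilinearly; mask membership by
# nearest voxel)
mc_moving_volume <- function(mask, field, n = 2e5, seed = 1, iters = 20) {
  grid <- field$grid
  lo <- grid$origin
  hi <- grid$origin + (grid$shape - 1) * grid$spacing
  comp <- lapply(1:3, function(k) field$vectors[, , , k])
  sample_u <- function(pts) {
    vapply(1:3, function(k)
      rdatrophy:::sample_volume_at(comp[[k]], grid, pts)$values,
      numeric(nrow(pts)))
  }
  rdatrophy:::local_seed(seed, {
    y <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
    x <- y
    for (it in seq_len(iters)) x <- y - sample_u(x)
    # nearest-voxel mask membership of the preimage
    idx <- sweep(sweep(x, 2, grid$origin), 2, grid$spacing, "/")
    idx <- round(idx) + 1
    ok <- idx[, 1] >= 1 & idx[, 1] <= grid$shape[1] &
          idx[, 2] >= 1 & idx[, 2] <= grid$shape[2] &
          idx[, 3] >= 1 & idx[, 3] <= grid$shape[3]
    inside <- logical(n)
    lin <- (idx[ok, 3] - 1) * grid$shape[1] * grid$shape[2] +
           (idx[ok, 2] - 1) * grid$shape[1] + idx[ok, 1]
    inside[ok] <- as.numeric(mask)[lin] > 0.5
    box <- prod(hi - lo)
    mean(inside) * box
  })
}

# literal brute-force enumerator of valid quadruples: checks the two
# constraints (interval nesting, at most one shared endpoint) over all
# ordered pair-of-pairs directly
brute_force_quadruples <- function(times) {
  n <- length(times)
  out <- list()
  for (i1 in 1:n) for (i2 in 1:n) for (i3 in 1:n) for (i4 in 1:n) {
    if (i1 == i2 || i3 == i4) next
    loA <- min(times[c(i1, i2)]); hiA <- max(times[c(i1, i2)])
    loB <- min(times[c(i3, i4)]); hiB <- max(times[c(i3, i4)])
    nested <- (loA >= loB && hiA <= hiB) || (loB >= loA && hiB <= hiA)
    if (!nested) next
    shared <- length(intersect(unique(c(i1, i2)), unique(c(i3, i4))))
    if (shared > 1) next
    if (setequal(c(i1, i2), c(i3, i4))) next
    out[[length(out) + 1]] <- c(i1, i2, i3, i4)
  }
  if (!length(out)) return(matrix(integer(), 0, 4))
  do.call(rbind, out)
}

# concordance-count AUC oracle
brute_force_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exact one-sided rank-sum p-value by full enumeration of group assignments
exact_wilcoxon_less <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(n, nx)
  stats <- apply(combs, 2, function(ix) sum(r[ix]))
  mean(stats <= obs)
}

# cached default-spec cohort for cross-file reuse
.small_cohort_env <- new.env()
small_cohort <- function(n = 4, seed = 77) {
  key <- sprintf("c_%d_%d", n, seed)
  if (is.null(.small_cohort_env[[key]]))
    .small_cohort_env[[key]] <- generate_cohort(phantom_spec(), n, seed)
  .small_cohort_env[[key]]
}
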