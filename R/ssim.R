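#' Structural similarity between two volumes
#'
#' Volume-averaged SSIM with a Gaussian window, the standard quality-control
#' statistic for registered longitudinal scan pairs (pairs scoring below 0.6
#' are conventionally treated as misregistered and excluded). Both volumes
#' are rescaled jointly so the dynamic range is the joint max minus joint min
#' of the pair.
#'
#' @param a,b [scalar_volume()] objects on the same grid.
#' @param sigma Gaussian window standard deviation in voxels (default 1.5).
#' @param K1,K2 stabilization constants of the standard formulation.
#' @return scalar SSIM score in `[-1, 1]`; 1 for identical volumes.
#' @export
ssim3d <- function(a, b, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  stop_if_grid_mismatch(a$grid, b$grid, "ssim3d inputs")
  lo <- min(min(a$values), min(b$values))
  hi <- max(max(a$values), max(b$values))
  L <- 1
  if (hi > lo) {
    av <- (a$values - lo) / (hi - lo)
    bv <- (b$values - lo) / (hi - lo)
  } else {
    av <- a$values * 0
    bv <- b$values * 0
  }
  d <- a$grid$shape
  radius <- max(1L, as.integer(ceiling(3 * sigma)))
  blur <- function(v) array(.gaussian_blur3(as.numeric(v), d[1], d[2], d[3],
                                            sigma, radius), dim = d)
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  mu_a <- blur(av)
  mu_b <- blur(bv)
  var_a <- blur(av * av) - mu_a^2
  var_b <- blur(bv * bv) - mu_b^2
  cov_ab <- blur(av * bv) - mu_a * mu_b
  ssim_map <- ((2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2))
  mean(ssim_map)
}
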