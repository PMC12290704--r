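test_that("grid and container validation reject malformed inputs", {
  expect_error(image_grid(c(4, 4)), "shape")
  expect_error(image_grid(c(4, 4, 4), spacing = c(1, 0, 1)), "spacing")
  g <- tiny_grid(4)
  expect_error(scalar_volume(array(0, c(4, 4, 3)), g), "matching")
  expect_error(scalar_volume(array(NA_real_, c(4, 4, 4)), g), "finite")
  expect_error(displacement_field(array(0, c(4, 4, 4, 2)), g), "4D")
  bad <- array(1, c(4, 4, 4, 3)); bad[1, 1, 1, 2] <- 0.5
  expect_error(attention_maps(bad, g), "sum to 1")
  expect_equal(voxel_volume(image_grid(c(2, 2, 2), c(1, 1, 2))), 2)
})

test_that("NIfTI round trips preserve values bitwise and grids to 1e-6 mm", {
  g <- image_grid(c(7, 6, 5), spacing = c(1, 1, 2), origin = c(3.5, -2, 7))
  vol <- scalar_volume(array(rnorm(7 * 6 * 5), g$shape), g)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_identical(back$values, vol$values)
  expect_true(same_grid(back$grid, vol$grid, tol = 1e-6))

  fld <- displacement_field(array(rnorm(7 * 6 * 5 * 3), c(g$shape, 3)), g)
  f2 <- tempfile(fileext = ".nii.gz")
  write_field(fld, f2)
  back2 <- read_field(f2)
  expect_identical(back2$vectors, fld$vectors)
  expect_true(same_grid(back2$grid, fld$grid, tol = 1e-6))

  # 4D dialect (x, y, z, 3) is accepted too
  img <- RNifti::asNifti(array(fld$vectors, c(g$shape, 3)),
                         reference = list(pixdim = c(-1, g$spacing, 1, 1, 0, 0)))
  f3 <- tempfile(fileext = ".nii")
  RNifti::writeNifti(img, f3)
  back3 <- read_field(f3)
  expect_equal(back3$vectors, fld$vectors)
})

test_that("reading a 4D scalar or 2-component field raises a format error", {
  f <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f)
  expect_error(read_volume(f), "3D scalar")
  expect_error(read_field(f), "3-vector")
})

test_that("jacobian determinant: zero field, uniform contraction, refined oracle", {
  g <- tiny_grid(12)
  expect_equal(jacobian_determinant(zero_field(g))$det,
               array(1, g$shape))
  expect_error(jacobian_determinant(zero_field(image_grid(c(2, 5, 5)))),
               "degenerate|3 voxels")

  f <- uniform_scale_field(tiny_grid(16), 0.9)
  J <- jacobian_determinant(f)
  expect_equal(J$det[8, 8, 8], 0.9^3, tolerance = 1e-12)
  expect_equal(max(abs(J$det - 0.729)), 0, tolerance = 1e-9)

  # random smooth fields vs an analytic central-difference oracle at half
  # the grid step, interior voxels
  for (seed in 1:3) {
    g <- tiny_grid(14)
    spec <- bump_field_spec(g, amplitude = 1.2, seed = seed)
    fld <- bump_field_on_grid(spec, g)
    J <- jacobian_determinant(fld)$det
    co <- rdatrophy:::grid_coordinates(g)
    interior <- array(FALSE, g$shape)
    interior[2:13, 2:13, 2:13] <- TRUE
    pts <- cbind(co$x[interior], co$y[interior], co$z[interior])
    oracle <- bump_field_detj(spec, pts, h = 0.5)
    expect_lt(max(abs(J[interior] - oracle)), 1e-2)
  }
})

test_that("region volumes: identity, analytic contraction, and MC oracle", {
  g <- tiny_grid(24)
  mask <- ball_mask(g, 8)
  z <- zero_field(g)
  rv <- region_volumes(mask, z)
  expect_identical(rv[["v_fixed"]], rv[["v_moving"]])

  f <- uniform_scale_field(g, 0.9)
  rv <- region_volumes(mask, f)
  expect_equal(rv[["v_moving"]] / rv[["v_fixed"]], 0.729, tolerance = 0.02)

  expect_error(region_volumes(ball_mask(tiny_grid(12), 4), f), "mismatch")

  spec <- bump_field_spec(g, amplitude = 1.5, seed = 5)
  fld <- bump_field_on_grid(spec, g)
  rv <- region_volumes(mask, fld)
  mc <- mc_moving_volume(mask, fld, n = 2e5, seed = 6)
  expect_equal(rv[["v_moving"]], mc, tolerance = 0.02)
})

test_that("composition of uniform scalings multiplies volume ratios", {
  g <- tiny_grid(20)
  mask <- ball_mask(g, 6)
  s1 <- 0.95; s2 <- 0.9
  f12 <- uniform_scale_field(g, s1 * s2)  # analytic composition
  rv <- region_volumes(mask, f12)
  expect_equal(rv[["v_moving"]] / rv[["v_fixed"]], (s1 * s2)^3,
               tolerance = 0.03 * (s1 * s2)^3)
})

test_that("ssim3d: identity, symmetry, and noise behavior", {
  coh <- small_cohort()
  a <- cohort_scan(coh, 1, 1)
  expect_equal(ssim3d(a, a), 1.0, tolerance = 1e-12)

  b <- cohort_scan(coh, 2, 1)
  expect_equal(ssim3d(a, b), ssim3d(b, a), tolerance = 1e-8)

  # structured phantom vs independent white noise of equal variance
  nz <- rdatrophy:::local_seed(3, scalar_volume(
    array(rnorm(length(a$values), mean(a$values), sd(a$values)),
          a$grid$shape), a$grid))
  expect_lt(ssim3d(a, nz), 0.6)

  # same phantom plus mild noise (SNR 20) stays clearly above the QC bar
  c2 <- a
  c2$values <- c2$values + rdatrophy:::local_seed(4,
    rnorm(length(a$values), sd = sd(a$values) / 20))
  expect_gte(ssim3d(a, c2), 0.7)

  expect_error(ssim3d(a, scalar_volume(array(0, c(4, 4, 4)), tiny_grid(4))),
               "mismatch")
})
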