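test_that("spec validation rejects impossible designs", {
  expect_error(phantom_spec(rate_range = c(0.01, 0.2)), "exhaust")
  expect_error(phantom_spec(n_timepoints = c(1, 2)), "n_timepoints")
  expect_error(phantom_spec(
    fluid = list(center = c(24, 23, 23), radii = c(5, 6, 7))), "overlap")
})

test_that("cohorts are bitwise reproducible given spec + seed", {
  c1 <- generate_cohort(phantom_spec(), 3, seed = 42)
  c2 <- generate_cohort(phantom_spec(), 3, seed = 42)
  expect_identical(cohort_subjects(c1), cohort_subjects(c2))
  expect_identical(cohort_scan(c1, 2, 1)$values, cohort_scan(c2, 2, 1)$values)
  p1 <- cohort_pair(c1, 1, 1, 2); p2 <- cohort_pair(c2, 1, 1, 2)
  expect_identical(p1$field$vectors, p2$field$vectors)
  c3 <- generate_cohort(phantom_spec(), 3, seed = 43)
  expect_false(identical(cohort_scan(c1, 1, 1)$values,
                         cohort_scan(c3, 1, 1)$values))
})

test_that("zero rate gives identical timepoints up to noise and ~zero field", {
  spec <- phantom_spec(rate_range = c(0, 0))
  coh <- generate_cohort(spec, 1, seed = 9)
  p <- cohort_pair(coh, 1, 1, 2)
  expect_lt(max(abs(p$field$vectors)), 0.05)
  clean1 <- rdatrophy:::render_scan_clean(spec, 0, coh$subjects[[1]]$times[1])
  clean2 <- rdatrophy:::render_scan_clean(spec, 0, coh$subjects[[1]]$times[2])
  expect_equal(clean1$values, clean2$values)
})

test_that("mask volumes track the prescribed linear volume loss", {
  spec <- phantom_spec(rate_range = c(0.05, 0.05), n_timepoints = c(3, 3),
                       interval_range = c(0.25, 4))
  coh <- generate_cohort(spec, 2, seed = 31)
  for (j in 1:2) {
    s <- coh$subjects[[j]]
    # voxel-counted tissue mask ratio after elapsed time
    m0 <- rdatrophy:::pair_masks(spec, s$rate, 0, coh$grid)
    for (tp in 2:3) {
      t <- s$times[tp]
      mt <- rdatrophy:::pair_masks(spec, s$rate, t, coh$grid)
      expect_equal(sum(mt$shrink) / sum(m0$shrink), 1 - 0.05 * t,
                   tolerance = 0.03 / (1 - 0.05 * t))
      expect_equal(sum(mt$expand) / sum(m0$expand), 1 + 0.05 * t,
                   tolerance = 0.03)
    }
    # tissue volumes strictly decrease, fluid strictly increase along time
    tv <- vapply(s$times, function(t)
      sum(rdatrophy:::pair_masks(spec, s$rate, t, coh$grid)$shrink), 1)
    fv <- vapply(s$times, function(t)
      sum(rdatrophy:::pair_masks(spec, s$rate, t, coh$grid)$expand), 1)
    expect_true(all(diff(tv) < 0))
    expect_true(all(diff(fv) > 0))
  }
})

test_that("ground-truth field Jacobian integrates to the prescribed ratio", {
  coh <- small_cohort()
  for (j in c(1, 3)) {
    s <- coh$subjects[[j]]
    p <- cohort_pair(coh, j, 1, 2)
    J <- jacobian_determinant(p$field)
    rv <- region_volumes(p$masks$shrink, p$field, jacobian = J)
    expect_equal(rv[["v_moving"]] / rv[["v_fixed"]],
                 1 - s$rate * p$interval, tolerance = 0.03)
    rv2 <- region_volumes(p$masks$expand, p$field, jacobian = J)
    expect_equal(rv2[["v_moving"]] / rv2[["v_fixed"]],
                 1 + s$rate * p$interval, tolerance = 0.03)
  }
})

test_that("confounds: no-op, QC-passing warp, QC-failing severe artifacts", {
  coh <- small_cohort()
  a <- cohort_scan(coh, 1, 1)
  expect_identical(add_nonsystematic_confound(a, confound_config(), 5), a)

  warped <- add_nonsystematic_confound(
    a, confound_config(warp_amplitude = 1.5), 5)
  s <- ssim3d(a, warped)
  expect_lt(s, 1)
  expect_gte(s, 0.6)

  sev <- confound_config(artifact_prob = 1, artifact_intensity = 2,
                         artifact_frac = 0.5)
  scores <- vapply(1:10, function(seed)
    ssim3d(a, add_nonsystematic_confound(a, sev, seed)), 1)
  expect_gte(mean(scores < 0.6), 0.8)

  # confounds never alter ground-truth masks or fields
  spec_cf <- phantom_spec(confound = confound_config(warp_amplitude = 1))
  c_cf <- generate_cohort(spec_cf, 2, seed = 77)
  c_clean <- generate_cohort(phantom_spec(), 2, seed = 77)
  p1 <- cohort_pair(c_cf, 1, 1, 2); p2 <- cohort_pair(c_clean, 1, 1, 2)
  expect_identical(p1$field$vectors, p2$field$vectors)
  expect_identical(p1$masks, p2$masks)
})

test_that("manifest round trip regenerates the cohort exactly", {
  skip_if_not_installed("jsonlite")
  spec <- phantom_spec(grid_shape = c(24, 24, 24),
    tissue = list(center = c(8, 12, 12), radii = c(4.5, 5, 4)),
    fluid = list(center = c(18, 12, 12), radii = c(2.5, 3, 3)),
    n_timepoints = c(2, 3))
  coh <- generate_cohort(spec, 2, seed = 5)
  dir <- file.path(tempdir(), "cohort_out")
  man <- write_cohort(coh, dir, fields = FALSE)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(man), sum(cohort_subjects(coh)$n_timepoints))
  back <- read_cohort(file.path(dir, "cohort.json"))
  expect_identical(cohort_subjects(back), cohort_subjects(coh))
  expect_identical(cohort_scan(back, 1, 1)$values, cohort_scan(coh, 1, 1)$values)
  # scans on disk match the in-memory render
  v <- read_volume(file.path(dir, man$scan[1]))
  expect_equal(v$values, cohort_scan(coh, 1, 1)$values)
})
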