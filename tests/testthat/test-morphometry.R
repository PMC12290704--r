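gt_attention <- function(pair, grid) {
  ch <- array(0, c(grid$shape, 3))
  ch[, , , 1] <- pair$masks$shrink
  ch[, , , 2] <- pair$masks$expand
  ch[, , , 3] <- 1 - pair$masks$shrink - pair$masks$expand
  attention_maps(ch, grid)
}

test_that("pair change with the identity field is exactly zero", {
  coh <- small_cohort()
  p <- cohort_pair(coh, 1, 1, 2)
  att <- gt_attention(p, coh$grid)
  ch <- pair_change(att, zero_field(coh$grid), interval = p$interval)
  expect_identical(ch$a_shr, 0)
  expect_identical(ch$a_exp, 0)
  expect_identical(ch$a_pooled, 0)
  expect_equal(ch$v_base, sum(p$masks$shrink) + sum(p$masks$expand))
})

test_that("ground-truth attention recovers the analytic fractional change", {
  spec <- phantom_spec(rate_range = c(0.05, 0.05), n_timepoints = c(2, 2),
                       interval_range = c(2, 2))
  coh <- generate_cohort(spec, 1, seed = 3)
  p <- cohort_pair(coh, 1, 1, 2)
  expect_equal(p$interval, 2)
  att <- gt_attention(p, coh$grid)
  ch <- pair_change(att, p$field, p$interval)
  shr_fixed <- sum(p$masks$shrink)
  expect_lt(abs(ch$a_shr / shr_fixed - (-0.10)), 0.02)
  expect_lt(ch$a_shr, 0); expect_gt(ch$a_exp, 0); expect_lt(ch$a_pooled, 0)

  # reversed registration direction flips the sign
  pr <- cohort_pair(coh, 1, 2, 1)
  attr_ <- gt_attention(pr, coh$grid)
  chr <- pair_change(attr_, pr$field, pr$interval)
  expect_gt(chr$a_shr, 0)

  # approximate antisymmetry with attention held fixed
  ch2 <- pair_change(att, pr$field, pr$interval)
  expect_equal(ch2$a_pooled, -ch$a_pooled,
               tolerance = 0.05 * abs(ch$a_pooled))
})

test_that("annualized rate: single pair, exact OLS, input validation", {
  one <- data.frame(a_pooled = -20, v_base = 1000, interval = 2)
  expect_equal(annualized_rate(one), -0.01)

  three <- data.frame(a_pooled = c(-10, -20, -40), v_base = c(1000, 1000, 1000),
                      interval = c(1, 2, 4))
  expect_equal(annualized_rate(three), -0.01, tolerance = 1e-12)
  expect_equal(annualized_rate(three, intercept = FALSE), -0.01,
               tolerance = 1e-12)

  expect_error(annualized_rate(data.frame()), "no pair changes")
  expect_error(annualized_rate(data.frame(a_pooled = 1, v_base = 1,
                                          interval = 0)), "positive")
  mixed <- data.frame(a_pooled = c(-1, -2), v_base = c(10, 10),
                      interval = c(1, 2), anchor = c(1, 2))
  expect_error(annualized_rate(mixed), "mixed anchoring")
})

test_that("age adjustment removes a linear age trend", {
  set.seed(5)
  ages <- runif(50, 65, 85)
  # rates independent of age: adjustment ~ centering on the reference mean
  r0 <- rep(-0.02, 50)
  adj <- age_adjust(r0, ages)
  expect_equal(adj, r0 - mean(r0), tolerance = 1e-12)

  # exact linear dependence is removed entirely
  r1 <- 0.001 * ages
  expect_lt(max(abs(age_adjust(r1, ages))), 1e-10)

  # slope recovery under noise
  r2 <- 0.002 * ages + rnorm(50, sd = 0.001)
  fit <- lm(r2 ~ ages)
  expect_lt(abs(unname(coef(fit)[2]) - 0.002), 0.0005)
  resid_sd <- sd(age_adjust(r2, ages))
  expect_lt(resid_sd, 0.0015)

  expect_error(age_adjust(r0, ages, reference = 1:2), ">= 3")
  expect_error(age_adjust(r0, rep(70, 50)), "constant age")
})

test_that("ground-truth attention rates track simulated rates (Spearman >= 0.95)", {
  coh <- generate_cohort(phantom_spec(n_timepoints = c(3, 3)), 30, seed = 202)
  est <- numeric(30)
  truth <- numeric(30)
  for (j in 1:30) {
    s <- coh$subjects[[j]]
    changes <- lapply(2:3, function(tp) {
      p <- cohort_pair(coh, j, 1, tp)
      ch <- pair_change(gt_attention(p, coh$grid), p$field, p$interval)
      ch$anchor <- 1L
      ch
    })
    est[j] <- annualized_rate(changes)
    truth[j] <- s$rate
  }
  expect_gte(cor(-est, truth, method = "spearman"), 0.95)
})
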