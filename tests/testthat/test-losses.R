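test_that("STO loss: uninformative value, limits, and symmetry", {
  expect_equal(sto_loss(0, 0, 1), 2 * log(2), tolerance = 1e-15)
  expect_equal(sto_loss(0, 0, -1), 2 * log(2), tolerance = 1e-15)
  expect_lt(sto_loss(-10, 10, 1), 1e-8)   # correct signs, large magnitude
  expect_lt(sto_loss(10, -10, -1), 1e-8)
  expect_gt(sto_loss(10, -10, 1), 5)      # confidently wrong is punished
  expect_error(sto_loss(0, 0, 0), "\\+1 or -1")
  expect_error(sto_loss(Inf, 0, 1), "finite")

  # (a_shr, a_exp, y) and (-a_shr, -a_exp, -y) give identical loss
  set.seed(1)
  for (i in 1:50) {
    a <- rnorm(1, sd = 0.2); b <- rnorm(1, sd = 0.2)
    y <- sample(c(-1, 1), 1)
    expect_lt(abs(sto_loss(a, b, y) - sto_loss(-a, -b, -y)), 1e-10)
  }
})

test_that("STO loss is monotone in the correctly-signed direction", {
  a_grid <- seq(-0.5, 0.5, length.out = 21)
  l_shr <- vapply(a_grid, function(a) sto_loss(a, 0, 1), 1)
  # decreasing in -a_shr for y = +1 (non-strict at saturation)
  expect_true(all(diff(l_shr) >= 0))
  expect_true(all(diff(l_shr[a_grid > -0.1 & a_grid < 0.1]) > 0))
  l_exp <- vapply(a_grid, function(a) sto_loss(0, a, 1), 1)
  expect_true(all(diff(l_exp) <= 0))  # decreasing in +a_exp
  expect_true(all(diff(l_exp[a_grid > -0.1 & a_grid < 0.1]) < 0))
})

test_that("STO gradient matches finite differences", {
  for (y in c(-1, 1)) {
    g <- sto_loss(0.07, -0.03, y, grad = TRUE)
    eps <- 1e-7
    fd_s <- (sto_loss(0.07 + eps, -0.03, y) - sto_loss(0.07 - eps, -0.03, y)) / (2 * eps)
    fd_e <- (sto_loss(0.07, -0.03 + eps, y) - sto_loss(0.07, -0.03 - eps, y)) / (2 * eps)
    expect_equal(g$d_a_shr, fd_s, tolerance = 1e-5)
    expect_equal(g$d_a_exp, fd_e, tolerance = 1e-5)
  }
})

test_that("RISI probabilities: sharp assignment and the origin", {
  p <- risi_category_probs(1, 4)   # ratio 0.25, category 1
  expect_gt(p[1], 0.99)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # at the origin every sigmoid is 1/2, every cone product 1/4
  p0 <- risi_category_probs(0, 0)
  expect_equal(p0, rep(0.25, 4), tolerance = 1e-12)

  # representative point per category, both sign conventions
  for (s in c(1, -1)) {
    expect_equal(which.max(risi_category_probs(s * 0.1, s * 0.4)), 1L)
    expect_equal(which.max(risi_category_probs(s * 0.3, s * 0.4)), 2L)
    expect_equal(which.max(risi_category_probs(s * 0.6, s * 0.4)), 3L)
    expect_equal(which.max(risi_category_probs(s * 0.9, s * 0.3)), 4L)
  }
})

test_that("RISI probabilities are continuous and sign-flip invariant", {
  set.seed(2)
  for (i in 1:200) {
    a1 <- rnorm(1, sd = 0.3); a2 <- rnorm(1, sd = 0.3)
    p <- risi_category_probs(a1, a2)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(p, risi_category_probs(-a1, -a2), tolerance = 1e-12)
    # continuity: small perturbation gives small probability change
    p2 <- risi_category_probs(a1 + 1e-6, a2 - 1e-6)
    expect_lt(max(abs(p - p2)), 1e-3)
  }
})

test_that("RISI gradients match finite differences", {
  set.seed(3)
  for (i in 1:20) {
    a1 <- rnorm(1, sd = 0.2); a2 <- rnorm(1, sd = 0.2)
    r <- risi_category_probs(a1, a2, grad = TRUE)
    eps <- 1e-7
    fd1 <- (risi_category_probs(a1 + eps, a2) -
            risi_category_probs(a1 - eps, a2)) / (2 * eps)
    fd2 <- (risi_category_probs(a1, a2 + eps) -
            risi_category_probs(a1, a2 - eps)) / (2 * eps)
    expect_equal(r$d_a1, fd1, tolerance = 1e-4)
    expect_equal(r$d_a2, fd2, tolerance = 1e-4)
  }
})

test_that("RISI loss: proportional changes, wrong bins, boundary tie-break", {
  # changes exactly proportional to the true ratio, alpha large
  expect_lt(risi_loss(0.1, 0.4, 0.1, 0.4, true_ratio = 0.25), 0.02)
  # changes in the wrong bin (observed ratio 3, true 0.25)
  expect_gt(risi_loss(0.6, 0.2, 0.6, 0.2, true_ratio = 0.25), 3)
  # boundary ratios fall in the lower bin
  expect_identical(risi_target_bin(1), 2L)
  expect_identical(risi_target_bin(0.5), 1L)
  expect_identical(risi_target_bin(2), 3L)
  expect_identical(risi_target_bin(2.0001), 4L)
  l <- risi_loss(0.2, 0.25, 0.2, 0.25, true_ratio = 1)
  expect_true(is.finite(l))
  expect_error(risi_target_bin(0), "positive")
})

test_that("total loss composes the weighted branches", {
  expect_equal(total_loss(0.5, 0.5, 0.5), 1.5)
  expect_equal(total_loss(0.3, 0.4, 9, loss_weights(w_risi = 0)), 0.7)
  expect_equal(total_loss(9, 9, 0.25, loss_weights(w_sto = 0)), 0.25)
  expect_error(loss_weights(w_sto = -1), ">= 0")
})
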