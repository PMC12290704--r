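test_that("forward output satisfies the attention-map invariants", {
  g <- tiny_grid(16)
  net <- init_attention_net(attention_net_config(depth = 3, base_channels = 2,
                                                 seed = 11))
  fx <- scalar_volume(array(rnorm(prod(g$shape)), g$shape), g)
  mv <- scalar_volume(array(rnorm(prod(g$shape)), g$shape), g)
  att <- attention_forward(net, fx, mv)
  sums <- att$channels[, , , 1] + att$channels[, , , 2] + att$channels[, , , 3]
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_gte(min(att$channels), 0)
  expect_lte(max(att$channels), 1)
  expect_true(same_grid(att$grid, g))
  expect_error(attention_forward(net, fx,
    scalar_volume(array(0, c(8, 8, 8)), tiny_grid(8))), "mismatch")
})

test_that("temperature softmax saturates small logit gaps", {
  # logit gap g at temperature tau: winner prob = 1 / (1 + 2 exp(-tau g))
  # when the two losers tie
  z <- matrix(c(0.06, 0, 0), 3, 1)
  p <- rdatrophy:::softmax_temp(z, 100)
  expect_gte(p[1, 1], 0.995)
  expect_equal(p[1, 1], 1 / (1 + 2 * exp(-100 * 0.06)), tolerance = 1e-12)
  # AttentionMaps invariant: max channel >= 0.95 whenever the gap >= 0.06
  zr <- matrix(rnorm(30), 3)
  zr[1, ] <- apply(zr, 2, max) + 0.06  # enforce the gap
  pr <- rdatrophy:::softmax_temp(zr, 100)
  expect_true(all(apply(pr, 2, max) >= 0.95))
})

test_that("initialization and forward are deterministic given the seed", {
  cfg <- attention_net_config(depth = 2, base_channels = 3, seed = 21)
  n1 <- init_attention_net(cfg)
  n2 <- init_attention_net(cfg)
  expect_identical(n1$params, n2$params)
  g <- tiny_grid(8)
  fx <- scalar_volume(array(rnorm(512), g$shape), g)
  mv <- scalar_volume(array(rnorm(512), g$shape), g)
  a1 <- attention_forward(n1, fx, mv)
  a2 <- attention_forward(n2, fx, mv)
  expect_identical(a1$channels, a2$channels)
})

test_that("swapping fixed and moving changes the output", {
  g <- tiny_grid(16)
  net <- init_attention_net(attention_net_config(depth = 2, base_channels = 4,
                                                 seed = 2))
  fx <- scalar_volume(array(rnorm(prod(g$shape)), g$shape), g)
  mv <- scalar_volume(array(rnorm(prod(g$shape)), g$shape), g)
  a1 <- attention_forward(net, fx, mv)
  a2 <- attention_forward(net, mv, fx)
  expect_false(identical(a1$channels, a2$channels))
})

test_that("non-divisible extents are padded and cropped transparently", {
  g <- image_grid(c(18, 14, 10))
  net <- init_attention_net(attention_net_config(depth = 3, base_channels = 2,
                                                 seed = 4))
  fx <- scalar_volume(array(rnorm(prod(g$shape)), g$shape), g)
  mv <- scalar_volume(array(rnorm(prod(g$shape)), g$shape), g)
  att <- attention_forward(net, fx, mv)
  expect_identical(dim(att$channels), c(g$shape, 3L))
  sums <- att$channels[, , , 1] + att$channels[, , , 2] + att$channels[, , , 3]
  expect_lt(max(abs(sums - 1)), 1e-5)
})

test_that("checkpoints restore weights and config exactly", {
  net <- init_attention_net(attention_net_config(depth = 2, base_channels = 2,
                                                 seed = 8))
  f <- tempfile(fileext = ".rds")
  save_checkpoint(net, f, log = data.frame(epoch = 1, total = 0.5))
  back <- load_checkpoint(f)
  expect_identical(back$params, net$params)
  expect_identical(back$config, net$config)
  expect_equal(attr(back, "log")$total, 0.5)
})
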