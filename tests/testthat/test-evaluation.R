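test_that("STO accuracy: perfect, random, and grouped records", {
  rec <- data.frame(a_pooled = rep(-1, 10), interval = rep(2, 10))
  expect_equal(sto_accuracy(rec)$overall, 1.0)

  set.seed(11)
  n <- 1000
  rec2 <- data.frame(a_pooled = sample(c(-1, 1), n, replace = TRUE),
                     interval = sample(c(-2, 2), n, replace = TRUE))
  acc <- sto_accuracy(rec2)$overall
  expect_equal(acc, 0.5, tolerance = 0.05)

  grp <- rep(c("a", "b"), each = n / 2)
  by <- sto_accuracy(rec2, grp)$by_group
  expect_named(by, c("a", "b"))
  # zero pooled change counts as incorrect
  rec3 <- data.frame(a_pooled = 0, interval = 1)
  expect_equal(sto_accuracy(rec3)$overall, 0)
})

test_that("RISI accuracy: proportional, tie, and random cases", {
  q <- data.frame(ratio = c(2, 0.5, 4), a_pooled_1 = c(-4, -1, -8),
                  a_pooled_2 = c(-2, -2, -2))
  expect_equal(risi_accuracy(q), 1.0)  # |a| proportional to |interval|

  tie <- data.frame(ratio = 2, a_pooled_1 = -2, a_pooled_2 = -2)
  expect_equal(risi_accuracy(tie), 0)  # ties count as failures

  set.seed(12)
  n <- 1000
  rnd <- data.frame(ratio = sample(c(0.4, 2.5), n, replace = TRUE),
                    a_pooled_1 = rnorm(n), a_pooled_2 = rnorm(n))
  expect_equal(risi_accuracy(rnd), 0.5, tolerance = 0.05)
})

test_that("AUC equals brute-force concordance counting", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")

  set.seed(13)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    scores <- sample(1:8, n, replace = TRUE)  # ties on purpose
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels), brute_force_auc(scores, labels))
  }

  set.seed(14)
  expect_equal(roc_auc(rnorm(2000), sample(c(0, 1), 2000, replace = TRUE)),
               0.5, tolerance = 0.03)
})

test_that("rank-sum test matches exact enumeration for small samples", {
  set.seed(15)
  for (i in 1:8) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- round(rnorm(nx), 2); y <- round(rnorm(ny, 0.3), 2)
    if (any(duplicated(c(x, y)))) next  # exact path is tie-free
    res <- group_difference(c(x, y), c(rep("g", nx), rep("ref", ny)), "ref")
    expect_equal(res$p_value, exact_wilcoxon_less(x, y), tolerance = 1e-12)
  }
})

test_that("group differences: self-comparison, calibration direction", {
  set.seed(16)
  ref <- rnorm(30, -0.01, 0.01)
  res <- group_difference(c(ref, ref),
                          c(rep("ref", 30), rep("same", 30)), "ref")
  expect_equal(res$p_value, 0.5, tolerance = 0.25)
  expect_equal(res$auc, 0.5, tolerance = 0.15)

  fast <- rnorm(30, -0.04, 0.01)  # faster atrophy: more negative
  res2 <- group_difference(c(ref, fast),
                           c(rep("ref", 30), rep("fast", 30)), "ref")
  expect_lt(res2$p_value, 0.001)
  expect_gt(res2$auc, 0.9)
  expect_error(group_difference(1:3, rep("a", 3), "b"), "reference")
})

test_that("heatmap aggregation: identity warp reproduces the mask, N-invariance, coverage", {
  coh <- small_cohort()
  p <- cohort_pair(coh, 1, 1, 2)
  grid <- coh$grid
  ch <- array(0, c(grid$shape, 3))
  ch[, , , 1] <- p$masks$shrink
  ch[, , , 2] <- p$masks$expand
  ch[, , , 3] <- 1 - ch[, , , 1] - ch[, , , 2]
  att <- attention_maps(ch, grid)

  hm1 <- aggregate_heatmap(list(a = att), list(a = zero_field(grid)), grid)
  expect_equal(hm1$shrink, p$masks$shrink)
  expect_equal(hm1$expand, p$masks$expand)
  expect_true(all(hm1$coverage == 1))

  # identical attention across N pairs gives the same heatmap as N = 1
  hm3 <- aggregate_heatmap(list(a = att, b = att, c = att),
                           list(a = zero_field(grid), b = zero_field(grid),
                                c = zero_field(grid)), grid)
  expect_equal(hm3$shrink, hm1$shrink)
  expect_true(all(hm3$coverage == 3))
  expect_true(all(hm3$shrink >= 0 & hm3$shrink <= 1))

  # a missing warp is skipped with a warning
  expect_warning(
    hm2 <- aggregate_heatmap(list(a = att, b = att),
                             list(a = zero_field(grid)), grid),
    "skipped")
  expect_equal(hm2$shrink, hm1$shrink)

  # enrichment of the exact mask is strong
  expect_gt(heatmap_enrichment(hm1, p$masks$shrink, "shrink"), 5)
})

test_that("interval-window filtering selects the configured scenarios", {
  rec <- data.frame(a_pooled = rep(-1, 4),
                    interval = c(200, 365, 500, 900) / 365.25)
  w1 <- filter_interval_window(rec, c(180, 400))
  expect_equal(nrow(w1), 2L)
  w2 <- filter_interval_window(rec, c(400, 800))
  expect_equal(nrow(w2), 1L)
})
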