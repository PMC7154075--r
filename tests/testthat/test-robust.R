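test_that("two-group percentile bootstrap behaves at the boundaries", {
  # identical groups: no evidence
  r <- pb_two_group(c(1, 2, 3), c(1, 2, 3), n_boot = 500, seed = 1)
  expect_equal(r$statistic, 0)
  expect_gte(r$p, 0.5)
  # complete separation: every bootstrap difference positive, raw p 0,
  # reported p at the 1/B floor
  r <- pb_two_group(c(10, 10, 10), c(1, 1, 1), n_boot = 500, seed = 1)
  expect_equal(r$statistic, 9)
  expect_equal(r$p_raw, 0)
  expect_equal(r$p, 1 / 500)
  expect_equal(r$effect_r, 1)  # separation limit of r
  expect_error(pb_two_group(1, c(1, 2)), "insufficient")
})

test_that("two-group test is deterministic given a seed and exchangeable", {
  x <- rnorm(8); y <- rnorm(8, 0.5)
  a <- pb_two_group(x, y, n_boot = 300, seed = 42)
  b <- pb_two_group(x, y, n_boot = 300, seed = 42)
  expect_identical(a, b)
  # permuting observations within groups leaves the statistic unchanged
  d <- pb_two_group(sample(x), sample(y), n_boot = 300, seed = 99)
  expect_equal(d$statistic, a$statistic)
})

test_that("two-way bootstrap statistics follow the contrast algebra", {
  a <- rep(c("t1", "t2", "t3"), each = 6)
  b <- rep(rep(c("CT", "RT"), each = 3), 3)
  # all observations equal: all statistics 0, all p = 1
  r <- suppressWarnings(pb_two_way(rep(5, 18), a, b, n_boot = 200, seed = 1))
  expect_equal(r$statistic, rep(0, 3))
  expect_equal(r$p_raw, rep(1, 3))
  # pure additive trial shift, zero noise: interaction exactly 0,
  # B main effect exactly 0
  y <- rep(c(0, 3, 6), each = 6)
  r <- pb_two_way(y, a, b, n_boot = 200, seed = 1)
  expect_gt(r$statistic[r$factor == "A"], 0)
  expect_equal(r$statistic[r$factor == "B"], 0)
  expect_equal(r$statistic[r$factor == "interaction"], 0)
  # strong planted A effect is detected
  set.seed(3)
  y2 <- rnorm(18, mean = rep(c(0, 5, 10), each = 6))
  r2 <- pb_two_way(y2, a, b, n_boot = 500, seed = 7)
  expect_lt(r2$p[r2$factor == "A"], 0.05)
  expect_error(pb_two_way(1:4, c("a", "a", "b", "b"), c("x", "x", "x", "x")),
               "2 levels")
  expect_error(
    pb_two_way(1:6, c("a", "a", "a", "a", "b", "b"),
               c("x", "y", "x", "y", "x", "x")),
    "empty design cell"
  )
})

test_that("BH adjustment reproduces the step-up hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # order-preserving with the input vector
  p <- c(0.04, 0.001, 0.3, 0.01)
  q <- bh_adjust(p)
  expect_equal(order(q), order(p))
})

test_that("omega-squared matches an independent textbook decomposition", {
  # balanced 2x2, n = 2 per cell; oracle computed from explicit sums
  # of squares, no model-fitting machinery
  y <- c(1, 2, 4, 5, 2, 3, 8, 9)
  a <- factor(rep(c("a1", "a2"), each = 4))
  b <- factor(rep(rep(c("b1", "b2"), each = 2), 2))
  gm <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, interaction(a, b), mean)
  ss_a <- 4 * sum((ma - gm)^2)
  ss_b <- 4 * sum((mb - gm)^2)
  ss_cells <- 2 * sum((mab - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((y - gm)^2)
  mse <- (ss_tot - ss_cells) / 4          # df_error = 8 - 4
  oracle <- c(ss_a - 1 * mse, ss_b - 1 * mse, ss_ab - 1 * mse) /
    (ss_tot + mse)
  om <- omega_squared(y, a, b)
  expect_equal(om$omega_sq_raw, unname(oracle), tolerance = 1e-12)
  expect_equal(om$omega_sq, pmax(unname(oracle), 0))
  expect_error(omega_squared(rep(1, 8), a, b), "zero total variance")
})

test_that("r effect size follows sqrt(t^2/(t^2+df))", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  sp2 <- 1  # both groups have variance 1
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  expect_equal(effect_size_r(x, y), sqrt(t^2 / (t^2 + 4)))
  expect_equal(effect_size_r(c(0, 0, 0, 0), c(1, 1, 1, 1)), 1)
  expect_error(effect_size_r(c(1, 1), c(1, 1)), "zero total variance")
})

test_that("null omega-squared is near zero with identical group means", {
  set.seed(5)
  y <- rnorm(24)
  a <- rep(c("a1", "a2", "a3"), each = 8)
  b <- rep(rep(c("b1", "b2"), each = 4), 3)
  om <- omega_squared(y, a, b)
  expect_true(all(om$omega_sq < 0.3))
  expect_true(all(abs(om$omega_sq_raw) < 0.3))
})

test_that("BH keeps the realized FDR at or below nominal on valid p-values", {
  # 200 replicates of 20 uniform nulls + 10 strong alternatives
  set.seed(606)
  alpha <- 0.05
  v <- r <- 0
  for (i in 1:200) {
    p <- c(runif(20), rbeta(10, 0.05, 1))
    is_null <- rep(c(TRUE, FALSE), c(20, 10))
    q <- bh_adjust(p)
    v <- v + sum(q <= alpha & is_null)
    r <- r + sum(q <= alpha)
  }
  realized_fdr <- v / max(r, 1)
  se <- sqrt(alpha * (1 - alpha) / 200)
  expect_lte(realized_fdr, alpha + 3 * se)
})
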