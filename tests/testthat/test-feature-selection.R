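test_that("ANOVA keeps the requested count, best features first", {
  set.seed(1)
  X <- matrix(rnorm(40 * 100), 40, 100)
  y <- rep(c(0L, 1L), each = 20)
  s <- select_anova(X, y, percentile = 0.02)
  expect_equal(sum(s), 2)

  # a feature identical to the (coded) labels separates perfectly
  X[, 50] <- y
  s2 <- select_anova(X, y, percentile = 0.01)
  expect_true(s2[50])
  expect_equal(attr(s2, "pvalues")[50], 0)
})

test_that("ANOVA p-values match a direct two-group F computation", {
  X <- matrix(c(1.1, 0.3, 2.2, 4.0, 3.1, 5.2,
                0.0, 1.0, 0.5, 0.4, 0.9, 0.1), 6, 2)
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  s <- select_anova(X, y, percentile = 0.5)
  for (j in 1:2) {
    ref <- stats::anova(stats::lm(X[, j] ~ factor(y)))
    expect_equal(attr(s, "statistic")[j], ref$`F value`[1], tolerance = 1e-10)
    expect_equal(attr(s, "pvalues")[j], ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("RFE recovers planted informative features on a separable fixture", {
  set.seed(2)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 50), n, 50)
  X[, 10] <- y * 2 + rnorm(n, sd = 0.1)
  X[, 30] <- -y * 2 + rnorm(n, sd = 0.1)
  X <- scale(X)
  s <- select_rfe_lr(X, y, n_keep_fraction = 0.04, step_fraction = 0.1)
  expect_equal(sum(s), 2)
  expect_true(all(s[c(10, 30)]))
  # at every elimination round the planted features carry the largest
  # absolute coefficients, so they must survive to the end
  beta <- snpstab:::l1_logistic_coef(X, y, C = 1)
  expect_setequal(order(abs(beta), decreasing = TRUE)[1:2], c(10, 30))
})

test_that("RFE boundary arithmetic", {
  set.seed(3)
  X <- scale(matrix(rnorm(40 * 10), 40, 10))
  y <- rep(c(0L, 1L), 20)
  # n_keep == ncol: identity mask
  s <- select_rfe_lr(X, y, n_keep_fraction = 1, step_fraction = 0.5)
  expect_true(all(s))
  # a large step on the last round removes only down to n_keep
  s2 <- select_rfe_lr(X, y, n_keep_fraction = 0.65, step_fraction = 0.9)
  expect_equal(sum(s2), 7)
})

test_that("embedded L1 selection shrinks with the penalty", {
  set.seed(4)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  X <- scale(matrix(rnorm(n * 30), n, 30))
  X[, 5] <- scale(y + rnorm(n, sd = 0.3))

  # pure noise at strong regularization (small C): near-empty support
  noise <- scale(matrix(rnorm(n * 30), n, 30))
  s_noise <- select_rlr_l1(noise, y, C = 0.001)
  expect_lte(sum(s_noise), 1)

  # threshold 0 keeps everything with a nonzero coefficient
  s0 <- select_rlr_l1(X, y, C = 10, threshold = 0)
  expect_equal(sum(s0), sum(attr(s0, "coefficients") != 0))

  # support size is monotone non-decreasing in C over a sweep
  sizes <- vapply(c(0.001, 0.01, 0.1, 1, 10),
                  function(C) sum(select_rlr_l1(X, y, C = C)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_true(s0[5])
})
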