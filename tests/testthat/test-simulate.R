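test_that("genotype codes follow Hardy-Weinberg expectations", {
  cfg <- simulation_config(
    n_samples = 4000, n_snps_per_chromosome = c(40, rep(0, 21)),
    maf_range = c(0.5, 0.5), with_covariates = FALSE, seed = 1
  )
  g <- simulate_genotypes(cfg)
  # E[code] = 2 * MAF = 1 at MAF 0.5
  expect_lt(abs(mean(g$X) - 1), 0.02)
  # genotype frequencies near (0.25, 0.5, 0.25)
  expect_lt(abs(mean(g$X == 1) - 0.5), 0.03)
})

test_that("independent SNPs are uncorrelated; LD blocks match a Monte-Carlo oracle", {
  mean_adjacent_r <- function(X) {
    r <- vapply(seq_len(ncol(X) - 1),
                function(j) stats::cor(X[, j], X[, j + 1]), numeric(1))
    mean(r)
  }
  cfg0 <- simulation_config(
    n_samples = 3000, n_snps_per_chromosome = c(20, rep(0, 21)),
    maf_range = c(0.3, 0.3), ld_block_size = 1, with_covariates = FALSE,
    seed = 2
  )
  expect_lt(abs(mean_adjacent_r(simulate_genotypes(cfg0)$X)), 0.03)

  # oracle: an independent latent-Gaussian thresholding simulation of one
  # pair of SNPs sharing a factor with rho = 0.8, at large n
  rho <- 0.8; maf <- 0.3; n_mc <- 2e5
  set.seed(77)
  draw_pair <- function() {
    f <- rnorm(n_mc)
    z1 <- sqrt(rho) * f + sqrt(1 - rho) * rnorm(n_mc)
    z2 <- sqrt(rho) * f + sqrt(1 - rho) * rnorm(n_mc)
    cbind(z1 < qnorm(maf), z2 < qnorm(maf))
  }
  pair <- draw_pair() + draw_pair()
  r_oracle <- stats::cor(pair[, 1], pair[, 2])

  cfg1 <- simulation_config(
    n_samples = 5000, n_snps_per_chromosome = c(40, rep(0, 21)),
    maf_range = c(0.3, 0.3), ld_block_size = 4, ld_rho = 0.8,
    with_covariates = FALSE, seed = 3
  )
  g1 <- simulate_genotypes(cfg1)
  # adjacent within-block pairs (skip block boundaries at multiples of 4)
  within <- setdiff(seq_len(39), seq(4, 39, by = 4))
  r_obs <- mean(vapply(within, function(j) stats::cor(g1$X[, j], g1$X[, j + 1]),
                       numeric(1)))
  expect_lt(abs(r_obs - r_oracle), 0.05)
})

test_that("intercept calibration hits the target class fraction", {
  cfg <- simulation_config(
    n_samples = 2000, n_snps_per_chromosome = c(5, rep(0, 21)),
    class_fraction = 0.23, with_covariates = FALSE, seed = 4
  )
  cohort <- simulate_cohort(cfg)
  expect_lt(abs(mean(cohort$y) - 0.23), 0.02)
})

test_that("a planted causal SNP recovers its odds ratio", {
  cfg <- simulation_config(
    n_samples = 5000, n_snps_per_chromosome = c(30, rep(0, 21)),
    maf_range = c(0.3, 0.3),
    causal_snps = tibble::tibble(chrom = 1, index = 7, beta = log(2)),
    class_fraction = 0.3, with_covariates = FALSE, seed = 5
  )
  cohort <- simulate_cohort(cfg)
  fit <- stats::glm(cohort$y ~ cohort$X[, 7], family = stats::binomial())
  or <- exp(stats::coef(fit)[2])
  expect_gt(or, 1.7)
  expect_lt(or, 2.35)
})

test_that("the emulated cohort hits its class sizes", {
  cfg <- simulation_config(seed = 6, n_snps_per_chromosome = 5,
                           with_covariates = TRUE)
  cohort <- simulate_cohort(cfg)
  expect_equal(nrow(cohort$X), 178)
  expect_lte(abs(sum(cohort$y == 1L) - 41), 4)
  expect_named(cohort$covariates,
               c("gender", "smoker", "ecog", "histology", "treatment", "arm"))
})

test_that("the generator is deterministic under its seed", {
  cfg <- simulation_config(n_samples = 60, n_snps_per_chromosome = 4,
                           missing_rate = 0.05, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$X, b$X)
  expect_identical(a$y, b$y)
  expect_identical(a$covariates, b$covariates)
  cfg2 <- simulation_config(n_samples = 60, n_snps_per_chromosome = 4,
                            missing_rate = 0.05, seed = 12)
  expect_false(identical(simulate_cohort(cfg2)$X, a$X))
  # missing-rate injection lands near its target
  expect_lt(abs(mean(is.na(a$X)) - 0.05), 0.02)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(maf_range = c(0.2, 0.6)), "maf_range")
  expect_error(simulation_config(class_fraction = 0), "class_fraction")
  expect_error(
    simulation_config(n_snps_per_chromosome = 10, ld_block_size = 11),
    "block"
  )
  expect_error(
    simulation_config(n_snps_per_chromosome = 10,
                      causal_snps = tibble::tibble(chrom = 1, index = 11,
                                                   beta = 1)),
    "index"
  )
})
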