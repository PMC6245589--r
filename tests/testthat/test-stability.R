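make_partial <- function(splits, chrom = 1, fs = "anova",
                         classifier = "linear_svm", seed = 50) {
  spec <- pipeline_spec(fs, "none", classifier,
                        grid = default_grid(fs, classifier, reduced = TRUE))
  partial_analysis(splits, chrom, spec, seed = seed,
                   include_covariates = FALSE)
}

test_that("stability scores match a literal loop-and-count brute force", {
  d <- make_dataset(n0 = 50, n1 = 25, m = 20, chrom = 1, seed = 60)
  splits <- stratified_three_way_split(d, seed = 61)
  # stability set of 30 samples, 20 SNPs, S = 10
  stab <- splits$stability
  expect_equal(nrow(stab$X), 30)
  partial <- make_partial(splits)

  set.seed(62)
  subsamples <- replicate(10, {
    c(sample(which(stab$y == 0L), 16), sample(which(stab$y == 1L), 8))
  }, simplify = FALSE)

  res <- stability_scores(partial, stab, S = 10, T_frac = 0.8, seed = 63,
                          subsamples = subsamples)
  oracle <- brute_force_anova_scores(stab$X, stab$y, subsamples,
                                     keep_fraction = 0.02)
  expect_identical(res$score, oracle)
  expect_true(all(res$score >= 0 & res$score <= 10))
})

test_that("score bounds: never-selected is 0, always-selected is S", {
  d <- make_dataset(n0 = 30, n1 = 15, m = 10, seed = 64)
  # one SNP equal to the label dominates every ANOVA refit
  d$X[, 4] <- d$y * 2
  splits <- stratified_three_way_split(d, seed = 65)
  partial <- make_partial(splits)
  res <- stability_scores(partial, splits$stability, S = 12, T_frac = 0.8,
                          seed = 66)
  expect_equal(res$score[4], 12)   # ceil(2% of 10) = 1 slot, always won
  expect_true(all(res$score[-4] == 0))
})

test_that("stability subsamples are stratified and seeded", {
  d <- make_dataset(n0 = 40, n1 = 16, m = 12, seed = 67)
  splits <- stratified_three_way_split(d, seed = 68)
  partial <- make_partial(splits)
  a <- stability_scores(partial, splits$stability, S = 8, seed = 70)
  b <- stability_scores(partial, splits$stability, S = 8, seed = 70)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_identical(attr(a, "S"), 8L)
  expect_identical(attr(a, "best_params"), partial$best_params)
})

test_that("merge keeps exactly the threshold survivors, in genome order", {
  d <- make_dataset(n0 = 44, n1 = 22, m = 18, chrom = rep(1:3, each = 6),
                    seed = 72)
  splits <- stratified_three_way_split(d, seed = 73)
  spec <- pipeline_spec("anova", "none", "linear_svm",
                        grid = list(cost = 1))
  results <- lapply(1:3, function(chr) {
    partial <- partial_analysis(splits, chr, spec, seed = 74,
                                include_covariates = FALSE)
    stability_scores(partial, splits$stability, S = 6, seed = 74)
  })
  all_scores <- dplyr::bind_rows(lapply(results, tibble::as_tibble))

  m0 <- filter_and_merge(results, W = 0, splits,
                         include_covariates = FALSE)
  expect_setequal(m0$features$snp_id, all_scores$snp_id)  # vacuous threshold

  surv <- function(W) tryCatch(
    filter_and_merge(results, W, splits,
                     include_covariates = FALSE)$features$snp_id,
    error = function(e) character(0))
  s6 <- surv(6); s3 <- surv(3); s0 <- surv(0)
  expect_true(all(s6 %in% s3))
  expect_true(all(s3 %in% s0))

  # feature order: chromosome, then column order
  ord <- order(m0$features$chrom)
  expect_identical(m0$features$chrom, m0$features$chrom[ord])

  expect_error(filter_and_merge(results, W = 7, splits), "exceed S")
  # unreachable threshold on shuffled-label scores: explicit error
  null_results <- lapply(results, function(r) { r$score <- 0L; r })
  expect_error(filter_and_merge(null_results, W = 6, splits),
               "no features reach")
})

test_that("the final analysis uses final-mode fractions and never resamples the test set", {
  cohort <- signal_cohort()
  splits <- stratified_three_way_split(cohort, seed = 75)
  spec <- pipeline_spec("anova", "up", "linear_svm",
                        grid = list(cost = c(0.1, 1)))
  results <- lapply(1:3, function(chr) {
    partial <- partial_analysis(splits, chr, spec, seed = 76,
                                include_covariates = FALSE)
    stability_scores(partial, splits$stability, S = 10, seed = 76)
  })
  merged <- filter_and_merge(results, W = 5, splits,
                             include_covariates = FALSE)
  final <- final_analysis(merged, spec, seed = 77)
  expect_equal(final$model$spec$mode, "final")
  # final keep budget: 10% of the 90 genome-wide SNPs, capped at the merge
  keep_budget <- min(ncol(merged$train$X), ceiling(0.1 * 90))
  expect_lte(sum(final$model$support), keep_budget)
  # the evaluation covers every untouched test sample exactly once
  expect_equal(sum(final$report$confusion), nrow(splits$test$X))
  # hyper-parameters may legitimately differ between partial and final fits
  expect_true(is.numeric(final$model$best_params$cost))
})

test_that("an all-constant chromosome yields an empty-support partial model with a warning", {
  d <- make_dataset(n0 = 30, n1 = 15, m = 6, seed = 78)
  d$X[, d$snp_map$chrom == 1] <- 2  # degenerate chromosome
  splits <- stratified_three_way_split(d, seed = 79)
  spec <- pipeline_spec("anova", "none", "linear_svm", grid = list(cost = 1))
  expect_warning(
    partial <- partial_analysis(splits, 1, spec, seed = 80,
                                include_covariates = FALSE),
    "empty support"
  )
  expect_equal(sum(partial$support), 0)
})
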