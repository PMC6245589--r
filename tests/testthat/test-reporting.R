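test_that("per-class metrics follow confusion-matrix arithmetic", {
  # shaped like a 36-sample test set: TN 27, FP 4, FN 4, TP 1
  truth <- c(rep(0L, 31), rep(1L, 5))
  pred <- c(rep(0L, 27), rep(1L, 4), rep(0L, 4), 1L)
  m <- weighted_f1(truth, pred)
  bc <- m$by_class
  expect_equal(bc$recall[bc$class == 0], 27 / 31)
  expect_equal(bc$precision[bc$class == 0], 27 / 31)
  expect_equal(bc$recall[bc$class == 1], 1 / 5)
  expect_equal(bc$precision[bc$class == 1], 1 / 5)
  expect_equal(bc$f1[bc$class == 1], 0.2)
})

test_that("evaluation reports are recomputable from their confusion matrix", {
  cohort <- signal_cohort()
  splits <- stratified_three_way_split(cohort, seed = 90)
  view <- dataset_view(splits$train)
  spec <- pipeline_spec("anova", "none", "linear_svm", mode = "final",
                        grid = list(cost = 1))
  fit <- fit_pipeline_cv(view, spec, seed = 91)
  rep <- evaluate(fit, dataset_view(splits$test),
                  train_view = view)
  cm <- rep$confusion
  expect_equal(sum(cm), nrow(splits$test$X))
  # per-class recalls = diagonal / row sums
  expect_equal(rep$by_class$recall[rep$by_class$class == 0],
               cm[["tn"]] / (cm[["tn"]] + cm[["fp"]]))
  expect_equal(rep$by_class$recall[rep$by_class$class == 1],
               cm[["tp"]] / (cm[["tp"]] + cm[["fn"]]))
  # weighted test F1 reproducible from the matrix
  n0 <- cm[["tn"]] + cm[["fp"]]; n1 <- cm[["fn"]] + cm[["tp"]]
  p0 <- cm[["tn"]] / (cm[["tn"]] + cm[["fn"]])
  r0 <- cm[["tn"]] / n0
  f0 <- 2 * p0 * r0 / (p0 + r0)
  p1 <- if (cm[["tp"]] + cm[["fp"]] > 0) cm[["tp"]] / (cm[["tp"]] + cm[["fp"]]) else 0
  r1 <- cm[["tp"]] / n1
  f1 <- if (p1 + r1 > 0) 2 * p1 * r1 / (p1 + r1) else 0
  expect_equal(rep$test_f1, (n0 * f0 + n1 * f1) / (n0 + n1))
  expect_true(is.finite(rep$train_f1))
  expect_s3_class(glance(rep), "tbl_df")
})

test_that("a class with no predicted members warns and scores zero", {
  d <- make_dataset(n0 = 60, n1 = 25, m = 4, seed = 92)
  d$X[] <- 2  # all-constant genotypes: empty support, majority prediction
  splits <- stratified_three_way_split(d, seed = 93)
  spec <- pipeline_spec("anova", "none", "linear_svm", grid = list(cost = 1))
  fit <- suppressWarnings(
    fit_pipeline_cv(dataset_view(splits$train), spec, seed = 94))
  expect_warning(rep <- evaluate(fit, dataset_view(splits$test)),
                 "class 1")
  expect_equal(rep$by_class$precision[rep$by_class$class == 1], 0)
  expect_equal(rep$by_class$f1[rep$by_class$class == 1], 0)
})

test_that("feature ranking follows the classifier-specific rules", {
  cohort <- signal_cohort()
  splits <- stratified_three_way_split(cohort, seed = 95)
  view <- dataset_view(splits$train, chrom = 1)

  # linear SVM: descending |weight| with the weight's sign
  fit_svm <- fit_pipeline_cv(view,
    pipeline_spec("anova", "none", "linear_svm", grid = list(cost = 1),
                  fs_keep_fraction = 0.2),
    seed = 96)
  rk <- rank_features(fit_svm)
  expect_true(all(diff(rk$value) <= 1e-12))
  w <- snpstab:::svm_weights(fit_svm$classifier_fit$fit)
  expect_setequal(rk$feature, names(w))
  expect_equal(rk$value, sort(abs(w), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_true(all(rk$sign %in% c("+", "-", ".")))
  expect_equal(unique(rk$source), "svm_weight")
  # the dominant weight's sign matches its univariate association with y
  top <- rk$feature[1]
  expect_equal(rk$sign[1],
               if (stats::cor(view$X[, top], view$y) > 0) "+" else "-")

  # knn + anova: ascending p-values, unsigned
  fit_knn <- fit_pipeline_cv(view,
    pipeline_spec("anova", "none", "knn", grid = list(n_neighbors = 5),
                  fs_keep_fraction = 0.2),
    seed = 97)
  rk2 <- rank_features(fit_knn)
  expect_true(all(diff(rk2$value) >= -1e-15))
  expect_equal(unique(rk2$source), "fs_pvalue")
  expect_true(all(rk2$sign == "."))

  # rf: impurity importances normalized to sum 1 before ranking
  fit_rf <- fit_pipeline_cv(view,
    pipeline_spec("rfe_lr", "none", "rf", grid = list(num_trees = 30),
                  fs_keep_fraction = 0.2, rfe_step_fraction = 0.3),
    seed = 98)
  rk3 <- rank_features(fit_rf)
  expect_equal(sum(rk3$value), 1, tolerance = 1e-9)
  expect_equal(unique(rk3$source), "rf_importance")
  # signs come from the wrapped logistic coefficients here
  expect_true(any(rk3$sign %in% c("+", "-")))
})

test_that("feature intersections follow set algebra", {
  grid <- tibble::tibble(
    fs = c("anova", "anova", "anova", "rfe_lr", "rfe_lr"),
    classifier = c("rf", "rf", "rf", "knn", "knn"),
    selected_features = list(c("a", "b", "c"), c("a", "b", "c"),
                             c("a", "b", "c"), c("a", "b"), c("b", "c"))
  )
  out <- feature_intersection(grid)
  expect_equal(out$n_match[out$fs == "anova"], 3)
  expect_equal(out$n_match[out$fs == "rfe_lr"], 1)
  expect_equal(out$n_experiments, c(3, 2))
})
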