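#' Specify one pipeline configuration
#'
#' A pipeline is six stages applied in order: mean imputation, zero-variance
#' filter, standardization, feature selection, class-imbalance resampling
#' (training folds only) and a classifier. One specification fixes the
#' feature-selection method, the sampling method, the classifier and the
#' hyper-parameter grid searched by stratified k-fold cross-validation with
#' weighted F1 as the scoring function.
#'
#' Feature-selection stringency differs between the per-chromosome
#' ("partial") analyses and the genome-wide ("final") analysis: by default
#' the partial mode keeps 2% of features (RFE step 4%), the final mode 10%
#' (RFE step 10%).
#'
#' @param fs_method `"anova"`, `"rfe_lr"` or `"rlr_l1"`.
#' @param sampling `"none"`, `"down"`, `"up"` or `"smote"`.
#' @param classifier `"linear_svm"`, `"rf"` or `"knn"`.
#' @param mode `"partial"` or `"final"`; sets the default feature-selection
#'   fractions.
#' @param grid Named list of hyper-parameter vectors to search; defaults to
#'   [default_grid()] for the chosen stages.
#' @param fs_keep_fraction Fraction of features the FS stage keeps
#'   (ANOVA percentile / RFE `n_features_to_select`).
#' @param rfe_step_fraction Fraction of current features RFE drops per
#'   round.
#' @param rlr_threshold Minimum absolute coefficient kept by the embedded
#'   L1 selector.
#' @param k Number of cross-validation folds (default 5).
#' @return A list of class `pipeline_spec`.
#' @export
pipeline_spec <- function(fs_method = c("anova", "rfe_lr", "rlr_l1"),
                          sampling = c("none", "down", "up", "smote"),
                          classifier = c("linear_svm", "rf", "knn"),
                          mode = c("partial", "final"),
                          grid = NULL,
                          fs_keep_fraction = NULL,
                          rfe_step_fraction = NULL,
                          rlr_threshold = 1e-10,
                          k = 5) {
  fs_method <- match.arg(fs_method)
  sampling <- match.arg(sampling)
  classifier <- match.arg(classifier)
  mode <- match.arg(mode)
  if (is.null(fs_keep_fraction)) {
    fs_keep_fraction <- if (mode == "partial") 0.02 else 0.10
  }
  if (is.null(rfe_step_fraction)) {
    rfe_step_fraction <- if (mode == "partial") 0.04 else 0.10
  }
  if (fs_keep_fraction <= 0 || fs_keep_fraction > 1) {
    abort("fs_keep_fraction must lie in (0, 1]")
  }
  if (is.null(grid)) grid <- default_grid(fs_method, classifier)
  valid_keys <- c(
    if (fs_method == "rlr_l1") "fs_C",
    switch(classifier, linear_svm = "cost", rf = "num_trees",
           knn = "n_neighbors")
  )
  if (!all(names(grid) %in% valid_keys) || !all(valid_keys %in% names(grid))) {
    abort(sprintf("grid keys must be exactly {%s} for this specification",
                  paste(valid_keys, collapse = ", ")))
  }
  structure(
    list(fs_method = fs_method, sampling = sampling, classifier = classifier,
         mode = mode, grid = grid, fs_keep_fraction = fs_keep_fraction,
         rfe_step_fraction = rfe_step_fraction, rlr_threshold = rlr_threshold,
         k = as.integer(k), scoring = "weighted_f1"),
    class = "pipeline_spec"
  )
}

#' Default hyper-parameter grids
#'
#' The standard search grids: SVM cost in powers of ten from 1e-3 to 1e3,
#' random-forest tree counts on a log-spaced ladder from 30 to 2999, KNN
#' neighbour counts 5-50, and the embedded L1 selector's inverse
#' regularization `C` from 100 to 10000. `reduced = TRUE` returns 2-point
#' grids for quick runs.
#'
#' @param fs_method,classifier Stage choices as in [pipeline_spec()].
#' @param reduced Use small grids (default `FALSE`).
#' @return Named list of parameter vectors.
#' @export
default_grid <- function(fs_method, classifier, reduced = FALSE) {
  grid <- list()
  if (fs_method == "rlr_l1") {
    grid$fs_C <- if (reduced) c(100, 1000) else c(100, 500, 1000, 1500, 5000, 10000)
  }
  grid <- c(grid, switch(classifier,
    linear_svm = list(cost = if (reduced) c(1, 10)
                      else c(0.001, 0.01, 0.1, 1, 10, 100, 1000)),
    rf = list(num_trees = if (reduced) c(30, 119)
              else c(30, 47, 75, 119, 189, 299, 475, 753, 1194, 1892, 2999)),
    knn = list(n_neighbors = if (reduced) c(5, 20) else c(5, 20, 35, 50))
  ))
  grid
}

#' @export
print.pipeline_spec <- function(x, ...) {
  cat(sprintf("<pipeline_spec> %s + %s + %s (%s mode, keep %.0f%%, k = %d)\n",
              x$fs_method, x$sampling, x$classifier, x$mode,
              100 * x$fs_keep_fraction, x$k))
  invisible(x)
}

# stratified k folds: per-class shuffle dealt round-robin; every fold must
# contain both classes
stratified_folds <- function(y, k, seed) {
  y <- as.integer(y)
  if (any(table(factor(y, levels = c(0L, 1L))) < k)) {
    abort(sprintf("a class has fewer than k = %d members; folds would miss a class", k))
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      members <- sample(which(y == cl))
      fold[members] <- rep_len(seq_len(k), length(members))
    }
  })
  fold
}

# fit the feature-selection stage on preprocessed data; returns the support
# over the preprocessed columns plus the ranking metric
fit_fs <- function(Xs, y, spec, fs_params = list()) {
  if (ncol(Xs) == 0) {
    s <- logical(0)
    return(list(support = s, pvalues = NULL, coefficients = NULL))
  }
  switch(spec$fs_method,
    anova = {
      s <- select_anova(Xs, y, spec$fs_keep_fraction)
      list(support = as.logical(s), pvalues = attr(s, "pvalues"),
           coefficients = NULL)
    },
    rfe_lr = {
      s <- select_rfe_lr(Xs, y, spec$fs_keep_fraction, spec$rfe_step_fraction)
      list(support = as.logical(s), pvalues = NULL,
           coefficients = attr(s, "coefficients"))
    },
    rlr_l1 = {
      s <- select_rlr_l1(Xs, y, fs_params$fs_C %||% 1000, spec$rlr_threshold)
      list(support = as.logical(s), pvalues = NULL,
           coefficients = attr(s, "coefficients"))
    }
  )
}

# support over the ORIGINAL columns for a frozen-parameter refit (the unit
# of work of stability scoring): preprocess + feature selection only
refit_support <- function(X, y, spec, fs_params = list()) {
  pp <- fit_preprocess(X)
  fs <- fit_fs(pp$X %||% X[, pp$keep, drop = FALSE], y, spec, fs_params)
  support <- rep(FALSE, ncol(X))
  support[which(pp$keep)[fs$support]] <- TRUE
  support
}

#' Fit a pipeline by stratified k-fold cross-validated grid search
#'
#' For every hyper-parameter setting and fold, all six stages are fitted on
#' the training folds only: imputation means, the variance mask,
#' standardization statistics and the feature-selection support come from
#' the training folds and are reused to transform the validation fold;
#' resampling is applied to the training folds only, so validation folds
#' keep the original class distribution. The best setting maximises mean
#' weighted F1 across folds (ties broken by grid order) and is refitted on
#' the full training view.
#'
#' @param view A [dataset_view()] of the training data.
#' @param spec A [pipeline_spec()].
#' @param seed Integer seed controlling folds, resampling and classifier
#'   randomness.
#' @return An object of class `fitted_pipeline` with the fitted stage
#'   statistics, the support mask, the best hyper-parameters and CV
#'   weighted-F1/precision/recall mean and standard deviation.
#' @export
fit_pipeline_cv <- function(view, spec, seed = 1) {
  X <- view$X
  y <- as.integer(view$y)
  if (is.null(y)) abort("training view must carry labels")
  grid <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0) abort("hyper-parameter grid is empty")
  fold <- stratified_folds(y, spec$k, child_seed(seed, 11))
  fs_key <- if (spec$fs_method == "rlr_l1") "fs_C" else NULL

  scores <- array(NA_real_, dim = c(nrow(grid), spec$k, 3),
                  dimnames = list(NULL, NULL, c("f1", "precision", "recall")))
  for (f in seq_len(spec$k)) {
    tr <- fold != f
    if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) {
      abort("a CV fold lost one of the classes")
    }
    pp <- suppressWarnings(fit_preprocess(X[tr, , drop = FALSE]))
    Xtr <- pp$X %||% X[tr, pp$keep, drop = FALSE]
    Xval <- apply_preprocess(X[!tr, , drop = FALSE], pp)
    ytr <- y[tr]
    fs_values <- if (is.null(fs_key)) list(NULL) else as.list(unique(grid[[fs_key]]))
    for (fv in fs_values) {
      fs_params <- if (is.null(fs_key)) list() else stats::setNames(list(fv), fs_key)
      fs <- fit_fs(Xtr, ytr, spec, fs_params)
      Xtr_fs <- Xtr[, fs$support, drop = FALSE]
      Xval_fs <- Xval[, fs$support, drop = FALSE]
      rs <- resample(Xtr_fs, ytr, spec$sampling,
                     seed = child_seed(seed, 20, f))
      rows <- if (is.null(fs_key)) seq_len(nrow(grid)) else which(grid[[fs_key]] == fv)
      for (g in rows) {
        params <- as.list(grid[g, , drop = FALSE])
        clf <- fit_classifier(rs$X, rs$y, spec$classifier, params,
                              seed = child_seed(seed, 30, f, g))
        pred <- predict_classifier(clf, Xval_fs)
        m <- weighted_f1(y[!tr], pred)
        scores[g, f, ] <- c(m$f1, m$precision, m$recall)
      }
    }
  }
  cv <- tibble::as_tibble(grid)
  cv$cv_f1_mean <- apply(scores[, , "f1", drop = FALSE], 1, mean)
  cv$cv_f1_sd <- apply(scores[, , "f1", drop = FALSE], 1, stats::sd)
  cv$cv_precision_mean <- apply(scores[, , "precision", drop = FALSE], 1, mean)
  cv$cv_precision_sd <- apply(scores[, , "precision", drop = FALSE], 1, stats::sd)
  cv$cv_recall_mean <- apply(scores[, , "recall", drop = FALSE], 1, mean)
  cv$cv_recall_sd <- apply(scores[, , "recall", drop = FALSE], 1, stats::sd)
  best_row <- which.max(cv$cv_f1_mean)  # first maximum = declared grid order
  best_params <- as.list(grid[best_row, , drop = FALSE])

  # refit the winning configuration on the full training view
  pp <- suppressWarnings(fit_preprocess(X))
  Xs <- pp$X %||% X[, pp$keep, drop = FALSE]
  fs_params <- if (is.null(fs_key)) list() else best_params["fs_C"]
  fs <- fit_fs(Xs, y, spec, fs_params)
  support <- rep(FALSE, ncol(X))
  support[which(pp$keep)[fs$support]] <- TRUE
  rs <- resample(Xs[, fs$support, drop = FALSE], y, spec$sampling,
                 seed = child_seed(seed, 40))
  clf <- fit_classifier(rs$X, rs$y, spec$classifier, best_params,
                        seed = child_seed(seed, 41))

  metric_full <- function(v) {
    out <- rep(NA_real_, ncol(X))
    out[pp$keep] <- v
    out
  }
  structure(
    list(
      spec = spec,
      feature_info = view$feature_info,
      feature_names = colnames(X),
      pp = pp[c("means", "keep", "center", "scale")],
      support = support,
      fs_pvalues = if (!is.null(fs$pvalues)) metric_full(fs$pvalues),
      fs_coefficients = if (!is.null(fs$coefficients)) metric_full(fs$coefficients),
      classifier_fit = clf,
      best_params = best_params,
      cv = cv,
      cv_f1_mean = cv$cv_f1_mean[best_row],
      cv_f1_sd = cv$cv_f1_sd[best_row],
      cv_precision_mean = cv$cv_precision_mean[best_row],
      cv_precision_sd = cv$cv_precision_sd[best_row],
      cv_recall_mean = cv$cv_recall_mean[best_row],
      cv_recall_sd = cv$cv_recall_sd[best_row],
      seed = as.integer(seed)
    ),
    class = "fitted_pipeline"
  )
}

#' @export
print.fitted_pipeline <- function(x, ...) {
  cat(sprintf("<fitted_pipeline> %s + %s + %s: %d/%d features selected\n",
              x$spec$fs_method, x$spec$sampling, x$spec$classifier,
              sum(x$support), length(x$support)))
  cat(sprintf("  CV weighted F1 %.3f +/- %.3f; best: %s\n",
              x$cv_f1_mean, x$cv_f1_sd,
              paste(names(x$best_params), unlist(x$best_params),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Predict class labels from a fitted pipeline
#'
#' Transforms new data with the training-time imputation means, variance
#' mask, standardization statistics and support mask, then applies the
#' fitted classifier. No statistic of the new data is used.
#'
#' @param object A `fitted_pipeline`.
#' @param newdata A [dataset_view()] (or numeric matrix with the same
#'   columns the pipeline was trained on).
#' @param ... Unused.
#' @return Integer vector of predicted labels in `{0, 1}`.
#' @export
predict.fitted_pipeline <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "dataset_view")) newdata$X else as.matrix(newdata)
  if (!identical(colnames(X), object$feature_names)) {
    if (!all(object$feature_names %in% colnames(X))) {
      abort("newdata is missing features the pipeline was trained on")
    }
    X <- X[, object$feature_names, drop = FALSE]
  }
  Xs <- apply_preprocess(X, object$pp)
  sel <- object$support[object$pp$keep]
  predict_classifier(object$classifier_fit, Xs[, sel, drop = FALSE])
}
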