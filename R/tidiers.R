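#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted pipeline into its per-feature table
#'
#' @param x A `fitted_pipeline`.
#' @param ... Unused.
#' @return Tibble with one row per input feature: `feature`, `is_snp`,
#'   `kept` (passed the variance filter), `selected` (in the FS support)
#'   and the FS metric (`pvalue` or `coefficient`) where available.
#' @export
tidy.fitted_pipeline <- function(x, ...) {
  out <- x$feature_info
  out$kept <- x$pp$keep
  out$selected <- x$support
  if (!is.null(x$fs_pvalues)) out$pvalue <- x$fs_pvalues
  if (!is.null(x$fs_coefficients)) out$coefficient <- x$fs_coefficients
  out
}

#' One-row summary of a fitted pipeline
#'
#' @param x A `fitted_pipeline`.
#' @param ... Unused.
#' @return One-row tibble with the stage instantiation, selected-feature
#'   count, CV metrics and best hyper-parameters (as a compact string).
#' @export
glance.fitted_pipeline <- function(x, ...) {
  tibble::tibble(
    fs = x$spec$fs_method, sampling = x$spec$sampling,
    classifier = x$spec$classifier, mode = x$spec$mode,
    n_features = length(x$support), n_selected = sum(x$support),
    cv_f1_mean = x$cv_f1_mean, cv_f1_sd = x$cv_f1_sd,
    cv_precision_mean = x$cv_precision_mean,
    cv_precision_sd = x$cv_precision_sd,
    cv_recall_mean = x$cv_recall_mean, cv_recall_sd = x$cv_recall_sd,
    best_params = paste(names(x$best_params), unlist(x$best_params),
                        sep = "=", collapse = ", ")
  )
}

#' Tidy an evaluation report into per-class metrics
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return Tibble with one row per class (`class`, `support`, `precision`,
#'   `recall`, `f1`).
#' @export
tidy.evaluation_report <- function(x, ...) {
  x$by_class
}

#' One-row summary of an evaluation report
#'
#' Columns mirror a model-selection summary table: CV mean +/- sd metrics,
#' train and test scores, per-class test metrics and the confusion matrix
#' cells.
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.evaluation_report <- function(x, ...) {
  bc <- x$by_class
  tibble::tibble(
    cv_f1_mean = x$cv_f1_mean, cv_f1_sd = x$cv_f1_sd,
    cv_precision_mean = x$cv_precision_mean,
    cv_precision_sd = x$cv_precision_sd,
    cv_recall_mean = x$cv_recall_mean, cv_recall_sd = x$cv_recall_sd,
    train_f1 = x$train_f1,
    test_f1 = x$test_f1, test_precision = x$test_precision,
    test_recall = x$test_recall,
    test_f1_0 = bc$f1[bc$class == 0], test_precision_0 = bc$precision[bc$class == 0],
    test_recall_0 = bc$recall[bc$class == 0],
    test_f1_1 = bc$f1[bc$class == 1], test_precision_1 = bc$precision[bc$class == 1],
    test_recall_1 = bc$recall[bc$class == 1],
    tn = x$confusion[["tn"]], fp = x$confusion[["fp"]],
    fn = x$confusion[["fn"]], tp = x$confusion[["tp"]]
  )
}

#' Tidy an experiment grid into a model-selection table
#'
#' One row per experiment, ordered by decreasing CV weighted F1 — the
#' layout of a "top models" summary table.
#'
#' @param x An `experiment_grid`.
#' @param ... Unused.
#' @return Tibble of per-experiment metrics.
#' @export
tidy.experiment_grid <- function(x, ...) {
  rows <- lapply(x$report, function(exp) {
    base <- tibble::tibble(fs = exp$fs, sampling = exp$sampling,
                           classifier = exp$classifier, status = exp$status)
    if (exp$status != "ok") return(base)
    dplyr::bind_cols(
      base,
      glance(exp$report),
      tibble::tibble(
        n_features = length(exp$selected_features),
        best_params = paste(names(exp$report$best_params),
                            unlist(exp$report$best_params),
                            sep = "=", collapse = ", ")
      )
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$cv_f1_mean))
}

#' Error-bar plot of CV weighted F1 across an experiment grid
#'
#' @param object An `experiment_grid`.
#' @param ... Unused.
#' @return A ggplot: one point per experiment (mean CV weighted F1) with
#'   +/- 1 sd error bars, ordered by score.
#' @export
autoplot.experiment_grid <- function(object, ...) {
  tbl <- tidy(object)
  tbl <- tbl[tbl$status == "ok", , drop = FALSE]
  tbl$label <- paste(tbl$fs, tbl$sampling, tbl$classifier, sep = " + ")
  tbl$label <- factor(tbl$label, levels = rev(tbl$label))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$cv_f1_mean, y = .data$label)) +
    ggplot2::geom_point(colour = "purple3") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$cv_f1_mean - .data$cv_f1_sd,
                   xmax = .data$cv_f1_mean + .data$cv_f1_sd),
      height = 0.3) +
    ggplot2::labs(x = "CV weighted F1 (mean ± sd)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of stability scores for one chromosome
#'
#' @param object A `stability_result`.
#' @param ... Unused.
#' @return A ggplot histogram of per-feature stability scores.
#' @export
autoplot.stability_result <- function(object, ...) {
  tbl <- tibble::as_tibble(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(binwidth = max(1, attr(object, "S") %/% 50),
                            fill = "grey30") +
    ggplot2::labs(
      x = sprintf("stability score (S = %d)", attr(object, "S")),
      y = "features",
      title = sprintf("Chromosome %d", attr(object, "chromosome"))) +
    ggplot2::theme_minimal()
}

#' Cross-validated permutation null for a pipeline
#'
#' Re-runs [fit_pipeline_cv()] on label-permuted copies of a training view
#' and returns the null distribution of the CV weighted F1 — the reference
#' band against which an observed score is judged. A leakage-safe pipeline
#' scores inside this band on permuted labels for every sampling method.
#'
#' @param view A [dataset_view()].
#' @param spec A [pipeline_spec()].
#' @param n_perm Number of label permutations (default 20).
#' @param seed Integer seed.
#' @param test_view Optional held-out [dataset_view()]; when given, each
#'   permuted model is also scored on it (with its true labels), yielding a
#'   null distribution for the test F1 as well.
#' @return Tibble with one row per permutation (`perm`, `cv_f1_mean` and,
#'   with a test view, `test_f1`).
#' @export
permutation_null <- function(view, spec, n_perm = 20, seed = 1,
                             test_view = NULL) {
  rows <- lapply(seq_len(n_perm), function(p) {
    pv <- view
    pv$y <- with_seed(child_seed(seed, 500, p), sample(view$y))
    fit <- fit_pipeline_cv(pv, spec, seed = child_seed(seed, 501, p))
    out <- tibble::tibble(perm = p, cv_f1_mean = fit$cv_f1_mean)
    if (!is.null(test_view)) {
      out$test_f1 <- weighted_f1(as.integer(test_view$y),
                                 predict(fit, test_view))$f1
    }
    out
  })
  dplyr::bind_rows(rows)
}
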