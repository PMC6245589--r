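#' Evaluate a fitted pipeline on held-out data
#'
#' Computes one predicted-label vector on the test view and derives every
#' metric from it: the confusion matrix (TN, FP, FN, TP with class 1 as
#' positive), overall weighted F1/precision/recall and the per-class
#' components. A class with zero predicted or true support scores 0 with a
#' warning rather than an error.
#'
#' @param model A `fitted_pipeline`.
#' @param test_view A [dataset_view()] untouched by any fitting.
#' @param train_view Optional training view, used to also report the
#'   training F1.
#' @return An object of class `evaluation_report`.
#' @export
evaluate <- function(model, test_view, train_view = NULL) {
  pred <- predict(model, test_view)
  truth <- as.integer(test_view$y)
  m <- weighted_f1(truth, pred)
  cm <- c(tn = sum(truth == 0L & pred == 0L),
          fp = sum(truth == 0L & pred == 1L),
          fn = sum(truth == 1L & pred == 0L),
          tp = sum(truth == 1L & pred == 1L))
  for (cl in c(0L, 1L)) {
    if (sum(pred == cl) == 0) {
      warn(sprintf("no samples predicted as class %d; its precision is 0", cl))
    }
  }
  train_f1 <- if (!is.null(train_view)) {
    weighted_f1(as.integer(train_view$y), predict(model, train_view))$f1
  } else {
    NA_real_
  }
  structure(
    list(
      confusion = cm,
      n_test = length(truth),
      test_f1 = m$f1, test_precision = m$precision, test_recall = m$recall,
      by_class = m$by_class,
      train_f1 = train_f1,
      cv_f1_mean = model$cv_f1_mean, cv_f1_sd = model$cv_f1_sd,
      cv_precision_mean = model$cv_precision_mean,
      cv_precision_sd = model$cv_precision_sd,
      cv_recall_mean = model$cv_recall_mean,
      cv_recall_sd = model$cv_recall_sd,
      best_params = model$best_params
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  CV weighted F1 %.3f +/- %.3f | test F1 %.3f (precision %.3f, recall %.3f)\n",
              x$cv_f1_mean, x$cv_f1_sd, x$test_f1, x$test_precision, x$test_recall))
  cat(sprintf("  confusion: TN %d FP %d FN %d TP %d\n",
              x$confusion["tn"], x$confusion["fp"], x$confusion["fn"],
              x$confusion["tp"]))
  invisible(x)
}

#' Rank the final model's features with effect signs
#'
#' The ranking source follows the classifier: a linear SVM ranks by
#' descending absolute weight with the weight's sign; a random forest ranks
#' by descending impurity importance, taking the sign from the
#' feature-selection coefficient when one exists (ANOVA gives no direction,
#' emitted as `"."`); KNN has no intrinsic metric, so the
#' feature-selection stage's metric is used — ascending ANOVA p-value
#' (unsigned) or descending absolute L1-logistic coefficient with its sign.
#'
#' @param model A fitted `fitted_pipeline` (final model).
#' @return Tibble of the selected features with columns `rank`, `feature`,
#'   `snp_id`, `chrom`, `pos`, `is_snp`, `value`, `sign` (`"+"`, `"-"` or
#'   `"."`) and `source`.
#' @export
rank_features <- function(model) {
  sel <- which(model$support)
  if (length(sel) == 0) {
    return(tibble::tibble(rank = integer(), feature = character(),
                          snp_id = character(), chrom = integer(),
                          pos = integer(), is_snp = logical(),
                          value = double(), sign = character(),
                          source = character()))
  }
  info <- model$feature_info[sel, , drop = FALSE]
  fs_coef <- if (!is.null(model$fs_coefficients)) model$fs_coefficients[sel]
  fs_pval <- if (!is.null(model$fs_pvalues)) model$fs_pvalues[sel]
  sign_of <- function(v) ifelse(v > 0, "+", ifelse(v < 0, "-", "."))

  clf <- model$spec$classifier
  if (clf == "linear_svm") {
    w <- rep(0, length(sel))
    if (model$classifier_fit$classifier == "linear_svm") {
      w <- svm_weights(model$classifier_fit$fit)
    }
    value <- abs(w); sgn <- sign_of(w); source <- "svm_weight"
    ord <- order(-value, seq_along(value))
  } else if (clf == "rf") {
    imp <- rep(0, length(sel))
    if (model$classifier_fit$classifier == "rf") {
      imp <- rf_importance(model$classifier_fit$fit)
      if (sum(imp) > 0) imp <- imp / sum(imp)
    }
    value <- as.numeric(imp)
    sgn <- if (!is.null(fs_coef)) sign_of(fs_coef) else rep(".", length(sel))
    source <- "rf_importance"
    ord <- order(-value, seq_along(value))
  } else {  # knn: fall back to the FS metric
    if (!is.null(fs_pval)) {
      value <- fs_pval; sgn <- rep(".", length(sel)); source <- "fs_pvalue"
      ord <- order(value, seq_along(value))
    } else {
      value <- abs(fs_coef); sgn <- sign_of(fs_coef); source <- "fs_coefficient"
      ord <- order(-value, seq_along(value))
    }
  }
  out <- tibble::tibble(
    feature = info$feature, snp_id = info$snp_id, chrom = info$chrom,
    pos = info$pos, is_snp = info$is_snp, value = unname(value),
    sign = unname(sgn), source = source
  )[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(out, "rank")
}

#' Intersection of selected features across experiments
#'
#' Groups experiment reports (by default by feature-selection method and
#' classifier, the grouping under which sampling is the only varying stage)
#' and reports, per group, the number of features common to every
#' experiment in the group.
#'
#' @param grid An `experiment_grid` from [run_experiment_grid()], or a data
#'   frame with columns `fs`, `classifier` and a list-column
#'   `selected_features`.
#' @param group Character vector of grouping columns
#'   (default `c("fs", "classifier")`).
#' @return Tibble with the grouping columns, `n_experiments`, the
#'   per-experiment feature counts and `n_match` (intersection
#'   cardinality).
#' @export
feature_intersection <- function(grid, group = c("fs", "classifier")) {
  tbl <- tibble::as_tibble(grid)
  tbl <- tbl[!vapply(tbl$selected_features, is.null, logical(1)), ]
  tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      n_experiments = dplyr::n(),
      feature_counts = paste(vapply(.data$selected_features, length, integer(1)),
                             collapse = " / "),
      n_match = length(Reduce(intersect, .data$selected_features)),
      .groups = "drop"
    )
}
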