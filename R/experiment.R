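#' Run configuration for the framework
#'
#' Collects every tunable of an end-to-end run. The defaults reproduce the
#' reference parametrization: a 20% test split then a 50/50
#' training/stability split, 5-fold CV scored by weighted F1, `S = 100`
#' stability subsamples of `T = 80%` of the stability set, stability
#' threshold `W = 100`, and the full 3 x 4 x 3 menus of feature-selection,
#' sampling and classification methods.
#'
#' @param test_frac,stability_frac Split fractions
#'   (see [stratified_three_way_split()]).
#' @param k CV folds.
#' @param S Stability subsample count.
#' @param T_frac Stability subsample fraction.
#' @param W Stability threshold (features need score >= W to merge).
#' @param fs_methods,samplings,classifiers Stage menus; the experiment grid
#'   is their cross-product.
#' @param reduced_grids Use the 2-point hyper-parameter grids of
#'   [default_grid()] (default `FALSE`).
#' @param grids Optional named list of hyper-parameter vectors (keys among
#'   `cost`, `num_trees`, `n_neighbors`, `fs_C`) overriding the default
#'   grid entries of the matching stages.
#' @param covariates Where clinical covariates enter the analysis:
#'   `"both"` (partial and final, the default), `"final"`, `"partial"` or
#'   `"none"`.
#' @param seed Master seed; one seed determines every random draw of a run.
#' @param jobs Worker count for chromosome-level parallelism (default 1).
#' @return A list of class `run_config`.
#' @export
run_config <- function(test_frac = 0.2, stability_frac = 0.5, k = 5,
                       S = 100, T_frac = 0.8, W = 100,
                       fs_methods = c("anova", "rfe_lr", "rlr_l1"),
                       samplings = c("none", "down", "up", "smote"),
                       classifiers = c("linear_svm", "rf", "knn"),
                       reduced_grids = FALSE, grids = NULL,
                       covariates = c("both", "final", "partial", "none"),
                       seed = 1, jobs = 1) {
  covariates <- match.arg(covariates)
  fs_methods <- match.arg(fs_methods, several.ok = TRUE)
  samplings <- match.arg(samplings, several.ok = TRUE)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (W > S) abort("W cannot exceed S")
  structure(
    list(test_frac = test_frac, stability_frac = stability_frac,
         k = as.integer(k), S = as.integer(S), T_frac = T_frac,
         W = as.integer(W), fs_methods = fs_methods, samplings = samplings,
         classifiers = classifiers, reduced_grids = isTRUE(reduced_grids),
         grids = grids,
         covariates = covariates, seed = as.integer(seed),
         jobs = as.integer(jobs)),
    class = "run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' The YAML round-trips: `read_run_config(write_run_config(cfg, path))`
#' reproduces `cfg` exactly.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run one experiment: the full partial-stability-merge-final chain
#'
#' For one (feature selection, sampling, classifier) instantiation: fit a
#' partial model per chromosome on the training set, score feature
#' stability on the stability set, merge features with score >= W across
#' chromosomes, refit and tune the final model on the merged training view
#' and evaluate it once on the merged test view.
#'
#' @param splits A `split_bundle`.
#' @param fs,sampling,classifier Stage instantiation.
#' @param config A [run_config()].
#' @return A list of class `experiment_report` with the stability results,
#'   merged features, final model, evaluation report and ranked features.
#' @export
run_experiment <- function(splits, fs, sampling, classifier, config) {
  grid <- default_grid(fs, classifier, reduced = config$reduced_grids)
  for (key in intersect(names(config$grids), names(grid))) {
    grid[[key]] <- config$grids[[key]]
  }
  spec <- pipeline_spec(
    fs_method = fs, sampling = sampling, classifier = classifier,
    mode = "partial", grid = grid, k = config$k
  )
  seed <- child_seed(config$seed, experiment_index(fs, sampling, classifier))
  chroms <- sort(unique(splits$train$snp_map$chrom))
  cov_partial <- config$covariates %in% c("both", "partial") &&
    !is.null(splits$train$covariates)
  cov_final <- config$covariates %in% c("both", "final") &&
    !is.null(splits$train$covariates)

  run_chrom <- function(chr) {
    partial <- partial_analysis(splits, chr, spec, seed = seed,
                                include_covariates = cov_partial)
    stability_scores(partial, splits$stability, S = config$S,
                     T_frac = config$T_frac, seed = seed)
  }
  results <- if (config$jobs > 1 &&
                 requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(chroms, run_chrom, mc.cores = config$jobs)
  } else {
    lapply(chroms, run_chrom)
  }
  merged <- filter_and_merge(results, W = config$W, splits = splits,
                             include_covariates = cov_final)
  final <- final_analysis(merged, spec, seed = seed)
  ranked <- rank_features(final$model)
  structure(
    list(fs = fs, sampling = sampling, classifier = classifier,
         status = "ok", stability = results, merged_features = merged$features,
         model = final$model, report = final$report, ranked_features = ranked,
         selected_features = ranked$feature[ranked$is_snp],
         seed = seed, config = config),
    class = "experiment_report"
  )
}

# deterministic per-experiment index inside the 3 x 4 x 3 cube
experiment_index <- function(fs, sampling, classifier) {
  fi <- match(fs, c("anova", "rfe_lr", "rlr_l1"))
  si <- match(sampling, c("none", "down", "up", "smote"))
  ci <- match(classifier, c("linear_svm", "rf", "knn"))
  (fi - 1L) * 12L + (si - 1L) * 3L + ci
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s + %s + %s [%s]\n",
              x$fs, x$sampling, x$classifier, x$status))
  if (x$status == "ok") print(x$report)
  invisible(x)
}

#' Run the full experiment grid
#'
#' Executes one experiment per element of the cross-product of the
#' configured feature-selection, sampling and classifier menus (the full
#' menus give 3 x 4 x 3 = 36 experiments). A failing experiment is recorded
#' as failed and the grid continues.
#'
#' @param splits A `split_bundle` (or a labelled [genotype_dataset()],
#'   which is split with the config's fractions and seed first).
#' @param config A [run_config()].
#' @return An `experiment_grid`: tibble with one row per experiment
#'   (`fs`, `sampling`, `classifier`, `status`, CV/test metrics, feature
#'   counts) and list-columns `report` and `selected_features`, sortable by
#'   `cv_f1_mean`.
#' @export
run_experiment_grid <- function(splits, config = run_config()) {
  if (inherits(splits, "genotype_dataset")) {
    splits <- stratified_three_way_split(
      splits, test_frac = config$test_frac,
      stability_frac = config$stability_frac, seed = config$seed)
  }
  combos <- expand.grid(
    classifier = config$classifiers, sampling = config$samplings,
    fs = config$fs_methods,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("fs", "sampling", "classifier")]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    fs <- combos$fs[i]; sampling <- combos$sampling[i]
    classifier <- combos$classifier[i]
    exp <- tryCatch(
      run_experiment(splits, fs, sampling, classifier, config),
      error = function(e) {
        structure(list(fs = fs, sampling = sampling, classifier = classifier,
                       status = "failed", message = conditionMessage(e)),
                  class = "experiment_report")
      }
    )
    ok <- exp$status == "ok"
    tibble::tibble(
      fs = fs, sampling = sampling, classifier = classifier,
      status = exp$status,
      cv_f1_mean = if (ok) exp$report$cv_f1_mean else NA_real_,
      cv_f1_sd = if (ok) exp$report$cv_f1_sd else NA_real_,
      test_f1 = if (ok) exp$report$test_f1 else NA_real_,
      n_features = if (ok) length(exp$selected_features) else NA_integer_,
      selected_features = list(if (ok) exp$selected_features),
      report = list(exp)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("experiment_grid", class(out))
  attr(out, "config") <- config
  out
}

#' Write an experiment report (or grid) to JSON
#'
#' Serializes the experiment's resolved configuration, seed, metrics,
#' confusion matrix, chosen hyper-parameters and ranked features. Byte
#' identical across runs with the same master seed.
#'
#' @param x An `experiment_report` or `experiment_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  to_list <- function(exp) {
    if (exp$status != "ok") {
      return(list(fs = exp$fs, sampling = exp$sampling,
                  classifier = exp$classifier, status = "failed",
                  message = exp$message))
    }
    rep <- exp$report
    list(
      fs = exp$fs, sampling = exp$sampling, classifier = exp$classifier,
      status = "ok", seed = exp$seed,
      config = unclass(exp$config),
      metrics = list(
        cv_f1_mean = rep$cv_f1_mean, cv_f1_sd = rep$cv_f1_sd,
        cv_precision_mean = rep$cv_precision_mean,
        cv_precision_sd = rep$cv_precision_sd,
        cv_recall_mean = rep$cv_recall_mean, cv_recall_sd = rep$cv_recall_sd,
        train_f1 = rep$train_f1, test_f1 = rep$test_f1,
        test_precision = rep$test_precision, test_recall = rep$test_recall,
        by_class = rep$by_class
      ),
      confusion = as.list(rep$confusion),
      best_params = rep$best_params,
      n_features = length(exp$selected_features),
      ranked_features = exp$ranked_features
    )
  }
  obj <- if (inherits(x, "experiment_grid")) {
    lapply(x$report, to_list)
  } else {
    to_list(x)
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write per-chromosome stability scores as TSV
#'
#' @param results List of `stability_result` objects.
#' @param path Output TSV path (`snp_id`, `chrom`, `pos`, `score`).
#' @return `path`, invisibly.
#' @export
write_stability_tsv <- function(results, path) {
  tbl <- dplyr::bind_rows(lapply(results, tibble::as_tibble))
  tbl <- tbl[tbl$is_snp, c("snp_id", "chrom", "pos", "score")]
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tbl, path)
  invisible(path)
}
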