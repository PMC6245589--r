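#' Per-chromosome partial analysis
#'
#' Runs the cross-validated grid search of [fit_pipeline_cv()] on the
#' training set restricted to one chromosome's SNPs (plus covariates when
#' requested). The result feeds stability scoring; with 22 autosomes an
#' experiment runs 22 partial analyses.
#'
#' @param splits A `split_bundle` from [stratified_three_way_split()].
#' @param chrom Chromosome (1-22) under analysis.
#' @param spec A [pipeline_spec()] in `"partial"` mode.
#' @param seed Integer seed.
#' @param include_covariates Carry covariate columns into the chromosome
#'   view (default `TRUE` when present).
#' @return A `fitted_pipeline` tagged with the chromosome.
#' @export
partial_analysis <- function(splits, chrom, spec, seed = 1,
                             include_covariates = !is.null(splits$train$covariates)) {
  view <- dataset_view(splits$train, chrom = chrom,
                       include_covariates = include_covariates)
  fit <- fit_pipeline_cv(view, spec, seed = child_seed(seed, 1000, chrom))
  if (sum(fit$support) == 0) {
    warn(sprintf("chromosome %d: empty support after feature selection", chrom))
  }
  fit$chromosome <- as.integer(chrom)
  fit$include_covariates <- include_covariates
  fit
}

#' Stability scores over subsample refits on the independent stability set
#'
#' Every feature's score starts at zero. `S` stratified subsamples of
#' `ceiling(T * n)` stability-set samples are drawn without replacement; for
#' each subsample the partial model's pipeline is refitted with its frozen
#' best hyper-parameters (no re-tuning), and every feature in that refit's
#' feature-selection support gains one point. Scores range from 0 (never
#' selected) to `S` (selected in every refit); features dropped by a
#' refit's variance filter count as not selected.
#'
#' @param partial A `fitted_pipeline` from [partial_analysis()].
#' @param stability A [genotype_dataset()] — the stability set, disjoint
#'   from the training samples.
#' @param S Number of subsample refits (default 100).
#' @param T_frac Fraction of the stability set drawn per refit
#'   (default 0.8).
#' @param seed Integer seed.
#' @param subsamples Optional list of `S` integer index vectors into the
#'   stability set, overriding the internal stratified draws (useful to
#'   audit the scoring loop against an external count).
#' @return A `stability_result`: tibble with `feature`, `is_snp`, `snp_id`,
#'   `chrom`, `pos` and integer `score`; `S`, `T_frac`, the chromosome and
#'   the frozen hyper-parameters are carried as attributes.
#' @export
stability_scores <- function(partial, stability, S = 100, T_frac = 0.8,
                             seed = 1, subsamples = NULL) {
  view <- dataset_view(stability, chrom = partial$chromosome,
                       include_covariates = isTRUE(partial$include_covariates))
  if (!identical(colnames(view$X), partial$feature_names)) {
    abort("stability view features do not match the partial model's features")
  }
  X <- view$X
  y <- as.integer(view$y)
  n <- nrow(X)
  take <- as.integer(ceiling(T_frac * n))
  counts <- as.integer(table(factor(y, levels = c(0L, 1L))))
  alloc <- stratified_allocation(counts, take)
  if (any(alloc == 0)) {
    abort("stability subsample would miss a class; increase T or the stability set")
  }
  fs_params <- if (partial$spec$fs_method == "rlr_l1") {
    partial$best_params["fs_C"]
  } else {
    list()
  }
  if (!is.null(subsamples) && length(subsamples) != S) {
    abort("subsamples must supply one index vector per refit")
  }
  score <- integer(ncol(X))
  for (s in seq_len(S)) {
    idx <- if (!is.null(subsamples)) {
      subsamples[[s]]
    } else {
      with_seed(child_seed(seed, 2000, partial$chromosome, s), {
        c(sample(which(y == 0L))[seq_len(alloc[1])],
          sample(which(y == 1L))[seq_len(alloc[2])])
      })
    }
    support <- suppressWarnings(
      refit_support(X[idx, , drop = FALSE], y[idx], partial$spec, fs_params)
    )
    score <- score + support
  }
  out <- view$feature_info
  out$score <- as.integer(score)
  structure(out,
            class = c("stability_result", class(out)),
            S = as.integer(S), T_frac = T_frac,
            chromosome = partial$chromosome,
            best_params = partial$best_params,
            cv_f1_mean = partial$cv_f1_mean, cv_f1_sd = partial$cv_f1_sd)
}

#' Filter features by stability threshold and merge across chromosomes
#'
#' Keeps, from each chromosome, exactly the SNP features with stability
#' score at least `W`, and concatenates them (chromosome order, then column
#' order) into genome-wide "filtered/merged" training and test views.
#' Covariate columns contributed by multiple chromosome views are
#' deduplicated and appended once when requested.
#'
#' @param results List of `stability_result` objects (one per chromosome,
#'   all with the same `S`).
#' @param W Stability threshold; `W = S` keeps only features selected in
#'   every refit.
#' @param splits The `split_bundle` the experiment runs on.
#' @param include_covariates Append covariate columns to the merged views.
#' @return A list of class `merged_dataset` with `train` and `test`
#'   [dataset_view()]s, the surviving `features` tibble, `W` and `S`.
#' @export
filter_and_merge <- function(results, W, splits,
                             include_covariates = !is.null(splits$train$covariates)) {
  S_vals <- unique(vapply(results, attr, integer(1), "S"))
  if (length(S_vals) != 1) abort("all stability results must share S")
  if (W > S_vals) abort("W cannot exceed S")
  ord <- order(vapply(results, attr, integer(1), "chromosome"))
  surviving <- dplyr::bind_rows(lapply(results[ord], function(r) {
    tibble::as_tibble(r)[r$is_snp & r$score >= W, , drop = FALSE]
  }))
  if (nrow(surviving) == 0) {
    abort(sprintf("no features reach stability threshold W = %d in any chromosome", W))
  }
  build_view <- function(data) {
    cols <- match(surviving$snp_id, data$snp_map$snp_id)
    sub <- subset_dataset(data, snps = cols)
    dataset_view(sub, include_covariates = include_covariates)
  }
  train_view <- build_view(splits$train)
  # total variable count of the study (all SNPs + covariate columns): the
  # final-analysis keep percentage is quoted against this total
  n_total <- ncol(splits$train$X) +
    (ncol(train_view$X) - nrow(surviving))
  structure(
    list(train = train_view,
         test = build_view(splits$test),
         features = surviving, W = as.integer(W), S = S_vals,
         n_total_variables = n_total),
    class = "merged_dataset"
  )
}

#' @export
print.merged_dataset <- function(x, ...) {
  cat(sprintf("<merged_dataset> %d stable SNPs (W = %d / S = %d) across %d chromosomes\n",
              nrow(x$features), x$W, x$S, length(unique(x$features$chrom))))
  invisible(x)
}

#' Final genome-wide analysis on the merged feature set
#'
#' Refits the same pipeline instantiation (final-mode feature-selection
#' budget) by cross-validated grid search on the filtered/merged training
#' view, then evaluates it once on the filtered/merged test view; the test
#' set is never resampled. The final model's hyper-parameters may differ
#' from the partial models'.
#'
#' The final feature-selection budget is 10% of the study's *total*
#' variable count (the percentage the reference parametrization quotes
#' against the full data-set). Because a stability-thresholded merge is far
#' smaller than 10% of the genome-wide input, this budget retains the whole
#' merged feature set — the final selection step only binds when the merge
#' is unusually large relative to the input.
#'
#' @param merged A [filter_and_merge()] result.
#' @param spec The experiment's [pipeline_spec()]; its feature-selection
#'   budget is switched to final mode.
#' @param seed Integer seed.
#' @param final_keep_fraction Final-analysis keep percentage, quoted
#'   against the total variable count (default 0.10).
#' @return List with `model` (the final `fitted_pipeline`) and `report`
#'   (an `evaluation_report` on the test view).
#' @export
final_analysis <- function(merged, spec, seed = 1,
                           final_keep_fraction = 0.10) {
  n_merged <- ncol(merged$train$X)
  n_total <- merged$n_total_variables %||% n_merged
  keep_count <- min(n_merged, ceiling(final_keep_fraction * n_total))
  final_spec <- pipeline_spec(
    fs_method = spec$fs_method, sampling = spec$sampling,
    classifier = spec$classifier, mode = "final", grid = spec$grid,
    fs_keep_fraction = (keep_count - 0.5) / n_merged,
    rlr_threshold = spec$rlr_threshold, k = spec$k
  )
  model <- fit_pipeline_cv(merged$train, final_spec,
                           seed = child_seed(seed, 3000))
  report <- evaluate(model, merged$test, train_view = merged$train)
  list(model = model, report = report)
}
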