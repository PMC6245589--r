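#' Mean imputation of missing genotype codes
#'
#' Replaces every missing entry with the column mean. At fit time the means
#' are computed from the data being fitted; at transform time (validation or
#' test data) the training means must be passed back in so no test statistic
#' leaks into the model.
#'
#' @param X Numeric matrix, possibly with `NA` entries.
#' @param fitted_means Optional named numeric vector of training column
#'   means to reuse.
#' @return The imputed matrix, with the means used stored in
#'   `attr(, "means")`.
#' @export
impute_mean <- function(X, fitted_means = NULL) {
  if (is.null(fitted_means)) {
    fitted_means <- colMeans(X, na.rm = TRUE)
    if (anyNA(fitted_means) || any(is.nan(fitted_means))) {
      bad <- colnames(X)[which(is.nan(fitted_means) | is.na(fitted_means))[1]]
      abort(sprintf("column %s is entirely missing; cannot impute", bad))
    }
  }
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- fitted_means[idx[, 2]]
  }
  attr(X, "means") <- fitted_means
  X
}

#' Zero-variance column filter
#'
#' Drops exactly the columns that are constant on the fitting data; all
#' features with non-zero variance are kept.
#'
#' @param X Imputed numeric matrix.
#' @return Logical keep-mask over columns. Warns when every column is
#'   constant.
#' @export
variance_filter <- function(X) {
  v <- matrixStats_colVars(X)
  keep <- v > 0
  if (!any(keep)) warn("all columns have zero variance")
  keep
}

# population-variance column helper (n denominator not needed; > 0 test only)
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(0, ncol(X)))
  mu <- colMeans(X)
  colMeans(X^2) - mu^2
}

#' Standardize columns to zero mean and unit variance
#'
#' Population scaling (divides by the root mean squared deviation, `n`
#' denominator). At transform time the fit-time statistics are reused, so
#' transformed validation/test columns need not have mean zero.
#'
#' @param X Numeric matrix with no zero-variance columns at fit time.
#' @param fitted_stats Optional list with `center` and `scale` from a
#'   previous fit.
#' @return Standardized matrix with `attr(, "center")` and
#'   `attr(, "scale")`.
#' @export
standardize <- function(X, fitted_stats = NULL) {
  if (is.null(fitted_stats)) {
    center <- colMeans(X)
    scale <- sqrt(pmax(matrixStats_colVars(X), 0))
    if (any(scale == 0)) {
      abort("zero-variance column at fit time; apply variance_filter first")
    }
  } else {
    center <- fitted_stats$center
    scale <- fitted_stats$scale
  }
  Xs <- sweep(sweep(X, 2, center, `-`), 2, scale, `/`)
  attr(Xs, "center") <- center
  attr(Xs, "scale") <- scale
  Xs
}

# fit the three pre-processing stages on training data
fit_preprocess <- function(X) {
  Xi <- impute_mean(X)
  means <- attr(Xi, "means")
  keep <- variance_filter(Xi)
  Xk <- Xi[, keep, drop = FALSE]
  if (ncol(Xk) == 0) {
    return(list(means = means, keep = keep, center = numeric(0),
                scale = numeric(0)))
  }
  Xs <- standardize(Xk)
  list(means = means, keep = keep,
       center = attr(Xs, "center"), scale = attr(Xs, "scale"), X = Xs)
}

# apply fitted pre-processing to new data
apply_preprocess <- function(X, pp) {
  Xi <- impute_mean(X, fitted_means = pp$means)
  Xk <- Xi[, pp$keep, drop = FALSE]
  if (ncol(Xk) == 0) return(Xk)
  standardize(Xk, fitted_stats = list(center = pp$center, scale = pp$scale))
}
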