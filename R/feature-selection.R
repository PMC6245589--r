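#' ANOVA filter feature selection
#'
#' Ranks features by the one-way (two-group) F statistic of feature vs class
#' and keeps the `ceiling(percentile * ncol(X))` features with the smallest
#' p-values; ties are broken by column order.
#'
#' @param X Numeric matrix (standardized training data).
#' @param y Integer class labels in `{0, 1}`; both classes must be present.
#' @param percentile Fraction of features to keep (e.g. 0.02).
#' @return Logical support mask over columns, with per-feature `pvalues`
#'   and `statistic` attributes.
#' @export
select_anova <- function(X, y, percentile) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("both classes must be present for ANOVA")
  st <- anova_f(X, y)
  n_keep <- min(ncol(X), max(1L, as.integer(ceiling(percentile * ncol(X)))))
  ord <- order(st$p, seq_len(ncol(X)))
  support <- rep(FALSE, ncol(X))
  support[ord[seq_len(n_keep)]] <- TRUE
  attr(support, "pvalues") <- st$p
  attr(support, "statistic") <- st$f
  support
}

# vectorized two-group one-way ANOVA F statistic per column
anova_f <- function(X, y) {
  n <- nrow(X)
  g1 <- y == 1L
  n1 <- sum(g1); n0 <- n - n1
  m1 <- colMeans(X[g1, , drop = FALSE])
  m0 <- colMeans(X[!g1, , drop = FALSE])
  gm <- colMeans(X)
  ssb <- n0 * (m0 - gm)^2 + n1 * (m1 - gm)^2
  sst <- colSums(sweep(X, 2, gm, `-`)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[ssw == 0 & ssb > 0] <- Inf
  f[ssw == 0 & ssb == 0] <- 0
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  p[is.infinite(f)] <- 0
  list(f = f, p = p)
}

# L1-penalized logistic regression coefficients at a single regularization
# strength C (inverse regularization: larger C = weaker penalty), via the
# coordinate-descent lasso path with lambda = 1/(n * C)
l1_logistic_coef <- function(X, y, C, maxit = 1e5) {
  n <- nrow(X)
  lambda <- 1 / (n * C)
  if (ncol(X) == 1) {
    fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                           family = stats::binomial()))
    return(stats::coef(fit)[-1])
  }
  fit <- tryCatch(
    suppressWarnings(glmnet::glmnet(
      X, factor(y, levels = c(0L, 1L)), family = "binomial", alpha = 1,
      lambda = lambda, standardize = FALSE, maxit = maxit
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fit <- tryCatch(
      suppressWarnings(glmnet::glmnet(
        X, factor(y, levels = c(0L, 1L)), family = "binomial", alpha = 1,
        lambda = lambda, standardize = FALSE, maxit = maxit * 10
      )),
      error = function(e) abort("L1 logistic regression failed to converge")
    )
  }
  as.numeric(fit$beta[, 1])
}

#' Recursive feature elimination with L1 logistic regression
#'
#' Iteratively fits an L1-penalized logistic regression (fixed `C`) and
#' removes the fraction `step_fraction` of the current features with the
#' smallest absolute coefficients, until `ceiling(n_keep_fraction * ncol(X))`
#' features remain. The last round removes only as many features as needed.
#'
#' @param X Numeric matrix (standardized training data).
#' @param y Integer class labels in `{0, 1}`.
#' @param n_keep_fraction Fraction of features to retain (e.g. 0.02).
#' @param step_fraction Fraction of the current feature count removed per
#'   round (e.g. 0.04).
#' @param C Inverse regularization strength of the wrapped model
#'   (default 1).
#' @return Logical support mask with a `coefficients` attribute holding the
#'   wrapped model's coefficients for the surviving features (zeros
#'   elsewhere).
#' @export
select_rfe_lr <- function(X, y, n_keep_fraction, step_fraction, C = 1) {
  if (ncol(X) < 1) abort("need at least one feature")
  n_keep <- min(ncol(X), max(1L, as.integer(ceiling(n_keep_fraction * ncol(X)))))
  current <- seq_len(ncol(X))
  coefs <- rep(0, ncol(X))
  repeat {
    beta <- l1_logistic_coef(X[, current, drop = FALSE], y, C)
    coefs[current] <- beta
    if (length(current) <= n_keep) break
    n_drop <- max(1L, as.integer(floor(step_fraction * length(current))))
    n_drop <- min(n_drop, length(current) - n_keep)
    # smallest |coefficient| goes first; ties broken by later column first,
    # keeping earlier columns preferentially
    ord <- order(abs(beta), -seq_along(current))
    current <- sort(current[-ord[seq_len(n_drop)]])
  }
  support <- rep(FALSE, ncol(X))
  support[current] <- TRUE
  coefs[!support] <- 0
  attr(support, "coefficients") <- coefs
  support
}

#' Embedded feature selection by regularized L1 logistic regression
#'
#' Fits one L1-penalized logistic regression and keeps the features whose
#' absolute coefficient is greater than or equal to `threshold`.
#'
#' @param X Numeric matrix (standardized training data).
#' @param y Integer class labels in `{0, 1}`.
#' @param C Inverse regularization strength (> 0).
#' @param threshold Minimum absolute coefficient to keep a feature
#'   (default 1e-10).
#' @return Logical support mask with a `coefficients` attribute.
#' @export
select_rlr_l1 <- function(X, y, C, threshold = 1e-10) {
  if (C <= 0) abort("C must be positive")
  beta <- l1_logistic_coef(X, y, C)
  # a zero threshold still excludes exactly-zeroed coefficients
  support <- if (threshold <= 0) beta != 0 else abs(beta) >= threshold
  attr(support, "coefficients") <- beta
  support
}
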