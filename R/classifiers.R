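# Classifier wrappers: a uniform fit/predict interface over linear SVM
# (libsvm), random forest (ranger, impurity importance, single-threaded for
# determinism) and k-nearest neighbours. A feature-less input falls back to
# a majority-class predictor so degenerate chromosomes stay well-defined.

fit_classifier <- function(X, y, classifier, params, seed = 1) {
  y <- as.integer(y)
  if (ncol(X) == 0) {
    maj <- if (sum(y == 1L) > sum(y == 0L)) 1L else 0L
    return(structure(list(classifier = "majority", majority = maj),
                     class = "snpstab_classifier"))
  }
  fit <- switch(classifier,
    linear_svm = e1071::svm(
      x = X, y = factor(y, levels = c(0L, 1L)), kernel = "linear",
      cost = params$cost, scale = FALSE
    ),
    rf = ranger::ranger(
      x = X, y = factor(y, levels = c(0L, 1L)),
      num.trees = params$num_trees, importance = "impurity",
      seed = seed, num.threads = 1
    ),
    knn = list(X = X, y = y, k = min(params$n_neighbors, nrow(X))),
    abort(sprintf("unknown classifier: %s", classifier))
  )
  structure(list(classifier = classifier, fit = fit, seed = seed),
            class = "snpstab_classifier")
}

predict_classifier <- function(object, X) {
  if (object$classifier == "majority") {
    return(rep(object$fit$majority %||% object$majority, nrow(X)))
  }
  switch(object$classifier,
    linear_svm = as.integer(as.character(predict(object$fit, X))),
    rf = as.integer(as.character(
      predict(object$fit, data = as.data.frame(X), num.threads = 1)$predictions
    )),
    knn = with_seed(object$seed, as.integer(as.character(
      class::knn(train = object$fit$X, test = X,
                 cl = factor(object$fit$y, levels = c(0L, 1L)),
                 k = object$fit$k)
    )))
  )
}

# signed linear-SVM feature weights: w = t(coefs) %*% SV
svm_weights <- function(fit) {
  w <- drop(crossprod(fit$coefs, fit$SV))
  # libsvm orients the decision function by the first class seen (level 0);
  # flip so positive weights push toward class 1
  if (fit$levels[1] == "0") w <- -w
  w
}

rf_importance <- function(fit) {
  ranger::importance(fit)
}
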