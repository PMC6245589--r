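#' Class-imbalance resampling of training data
#'
#' Applied to training folds only — validation and test data always keep the
#' original class distribution. Methods: `"none"` (identity), `"down"`
#' (majority class subsampled without replacement to the minority size),
#' `"up"` (minority class sampled with replacement to the majority size) and
#' `"smote"` (minority class augmented to the majority size with synthetic
#' points drawn uniformly on the segment between a minority sample and one
#' of its k nearest minority neighbours; k defaults to 5 and is reduced to
#' `minority - 1` when the minority class is small).
#'
#' @param X Numeric training matrix.
#' @param y Integer class labels in `{0, 1}`; both classes must be present.
#' @param method One of `"none"`, `"down"`, `"up"`, `"smote"`.
#' @param seed Integer seed; results are deterministic given the seed.
#' @param k_neighbors SMOTE neighbour count (default 5).
#' @return List with resampled `X` and `y`.
#' @export
resample <- function(X, y, method = c("none", "down", "up", "smote"),
                     seed = 1, k_neighbors = 5) {
  method <- match.arg(method)
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("resampling needs both classes present")
  if (method == "none") return(list(X = X, y = y))
  counts <- table(factor(y, levels = c(0L, 1L)))
  minority <- if (counts[["0"]] <= counts[["1"]]) 0L else 1L
  majority <- 1L - minority
  min_idx <- which(y == minority)
  maj_idx <- which(y == majority)
  with_seed(seed, {
    if (method == "down") {
      keep_maj <- sample(maj_idx, length(min_idx))
      idx <- sort(c(min_idx, keep_maj))
      out <- list(X = X[idx, , drop = FALSE], y = y[idx])
    } else if (method == "up") {
      extra <- sample(min_idx, length(maj_idx) - length(min_idx), replace = TRUE)
      idx <- c(seq_along(y), extra)
      out <- list(X = X[idx, , drop = FALSE], y = y[idx])
    } else {
      n_new <- length(maj_idx) - length(min_idx)
      synth <- smote_points(X[min_idx, , drop = FALSE], n_new, k_neighbors)
      out <- list(X = rbind(X, synth), y = c(y, rep(minority, n_new)))
    }
  })
  rownames(out$X) <- NULL
  out
}

# synthesize n_new minority points: pick a random minority sample, then a
# random one of its k nearest minority neighbours (Euclidean), and
# interpolate uniformly along the segment between them
smote_points <- function(M, n_new, k_neighbors) {
  if (n_new <= 0) return(M[0, , drop = FALSE])
  n_min <- nrow(M)
  if (n_min < 2) abort("SMOTE needs at least 2 minority samples")
  k <- min(k_neighbors, n_min - 1L)
  d <- as.matrix(stats::dist(M))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  base <- sample.int(n_min, n_new, replace = TRUE)
  pick <- sample.int(k, n_new, replace = TRUE)
  gap <- runif(n_new)
  neigh <- nn[cbind(base, pick)]
  M[base, , drop = FALSE] + gap * (M[neigh, , drop = FALSE] - M[base, , drop = FALSE])
}
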