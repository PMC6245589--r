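#' @importFrom rlang %||% abort warn .data
#' @importFrom stats var qnorm rnorm runif rbinom plogis predict quantile
NULL

# Deterministic seed derivation: one master seed fans out to independent child
# seeds for chromosomes, folds, shuffles, experiments. Knuth-style integer
# mixing kept in double precision, result always in [1, 2^31 - 2].
child_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647
  s <- as.double(seed %% m)
  for (i in idx) {
    s <- (s * 48271 + as.double(i) * 16807 + 11) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Allocate `total` units across classes proportionally to `counts`, rounding
# half away from zero, then correcting to the exact total by adjusting classes
# in order of descending fractional distance (larger class wins ties).
stratified_allocation <- function(counts, total) {
  ideal <- counts * total / sum(counts)
  alloc <- round_half_away(ideal)
  gap <- total - sum(alloc)
  if (gap != 0) {
    frac <- ideal - floor(ideal)
    key <- if (gap > 0) -frac else frac
    ord <- order(key, -counts, seq_along(counts))
    i <- 1L
    while (gap != 0) {
      j <- ord[(i - 1L) %% length(counts) + 1L]
      step <- sign(gap)
      if (alloc[j] + step >= 0 && alloc[j] + step <= counts[j]) {
        alloc[j] <- alloc[j] + step
        gap <- gap - step
      }
      i <- i + 1L
    }
  }
  alloc <- pmin(pmax(alloc, 0), counts)
  stopifnot(sum(alloc) == total)
  alloc
}

#' Weighted F1, precision and recall for binary labels
#'
#' Per-class F1 is `2 * P * R / (P + R)`; the weighted score averages the
#' per-class values with weights proportional to the true class supports.
#' Classes with zero predicted or true support contribute a score of 0.
#'
#' @param truth Integer vector of true labels in `{0, 1}`.
#' @param pred Integer vector of predicted labels in `{0, 1}`.
#' @return Named list with `f1`, `precision`, `recall` (weighted) and
#'   per-class components `by_class` (tibble with one row per class).
#' @export
weighted_f1 <- function(truth, pred) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  classes <- c(0L, 1L)
  per <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    tibble::tibble(class = cl, support = sum(truth == cl),
                   precision = precision, recall = recall, f1 = f1)
  })
  by_class <- dplyr::bind_rows(per)
  w <- by_class$support / sum(by_class$support)
  list(
    f1 = sum(w * by_class$f1),
    precision = sum(w * by_class$precision),
    recall = sum(w * by_class$recall),
    by_class = by_class
  )
}

# evaluate an expression with a locally-seeded RNG, restoring global state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
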