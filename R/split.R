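#' Stratified three-way split into training, stability and test sets
#'
#' First splits the cohort into a test set and a "preliminary" set, then
#' splits the preliminary set into equal-purpose training and stability
#' sets. Both splits are stratified by class: the total part size is the
#' requested fraction rounded half away from zero, apportioned across the
#' two classes by proportional shares rounded the same way (largest-remainder
#' correction keeps the total exact). On a 178-sample cohort with a 137/41
#' class split the defaults give 36 test, then 71 training and 71 stability
#' samples.
#'
#' @param data A labelled [genotype_dataset()].
#' @param test_frac Fraction of samples held out for the test set
#'   (default 0.2).
#' @param stability_frac Fraction of the remaining preliminary set assigned
#'   to the stability set (default 0.5).
#' @param seed Integer seed; the same seed always reproduces the same split.
#' @return A list of class `split_bundle` with `train`, `stability` and
#'   `test` genotype datasets plus the `seed`.
#' @export
stratified_three_way_split <- function(data, test_frac = 0.2,
                                       stability_frac = 0.5, seed = 1) {
  if (is.null(data$y)) abort("dataset must carry class labels to be split")
  if (test_frac <= 0 || test_frac >= 1 || stability_frac <= 0 || stability_frac >= 1) {
    abort("split fractions must lie strictly between 0 and 1")
  }
  counts <- table(factor(data$y, levels = c(0L, 1L)))
  if (any(counts < 2)) abort("each class needs at least 2 members to stratify")

  first <- stratified_partition(data$y, test_frac, child_seed(seed, 1))
  test_idx <- first$part
  prelim_idx <- first$rest
  second <- stratified_partition(data$y[prelim_idx], stability_frac,
                                 child_seed(seed, 2))
  stability_idx <- prelim_idx[second$part]
  train_idx <- prelim_idx[second$rest]

  for (idx in list(train_idx, stability_idx, test_idx)) {
    if (length(unique(data$y[idx])) < 2) {
      abort("a class is too small to appear in every split part")
    }
  }
  structure(
    list(
      train = subset_dataset(data, samples = sort(train_idx)),
      stability = subset_dataset(data, samples = sort(stability_idx)),
      test = subset_dataset(data, samples = sort(test_idx)),
      seed = as.integer(seed)
    ),
    class = "split_bundle"
  )
}

# draw a stratified part of round_half_away(frac * n) samples; per-class
# shuffle then take the allocated head of each class
stratified_partition <- function(y, frac, seed) {
  n <- length(y)
  total <- as.integer(round_half_away(frac * n))
  counts <- as.integer(table(factor(y, levels = c(0L, 1L))))
  alloc <- stratified_allocation(counts, total)
  part <- integer(0)
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      members <- which(y == cl)
      take <- alloc[cl + 1L]
      if (take > 0) part <- c(part, sample(members)[seq_len(take)])
    }
  })
  list(part = part, rest = setdiff(seq_len(n), part))
}

#' @export
print.split_bundle <- function(x, ...) {
  cat(sprintf(
    "<split_bundle> train %d / stability %d / test %d samples (seed %d)\n",
    nrow(x$train$X), nrow(x$stability$X), nrow(x$test$X), x$seed))
  invisible(x)
}
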