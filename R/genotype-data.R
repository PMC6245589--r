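#' Genotype dataset container
#'
#' Bundles an additively-coded genotype matrix (samples in rows, SNPs in
#' columns, entries counting minor alleles: 0, 1, 2 or `NA`) with its SNP map
#' (id, autosome, 1-based position), optional clinical covariates and an
#' optional binary response label (0 = responder, 1 = non-responder).
#'
#' @param X Numeric matrix of additive genotype codes; non-missing entries
#'   must be 0, 1 or 2. Column names, when absent, are taken from `snp_map`.
#' @param snp_map Data frame with columns `snp_id`, `chrom` (integer 1-22)
#'   and `pos` (1-based bp); optional `ref`/`alt` allele columns. One row per
#'   column of `X`, in column order.
#' @param y Optional integer vector of class labels in `{0, 1}`, one per
#'   sample.
#' @param covariates Optional data frame of per-sample clinical variables,
#'   one row per sample.
#' @param sample_ids Character vector of sample identifiers; defaults to
#'   `rownames(X)` or `sample_1 ... sample_n`.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(X, snp_map, y = NULL, covariates = NULL,
                             sample_ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  snp_map <- tibble::as_tibble(snp_map)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(X) %||% paste0("sample_", seq_len(nrow(X)))
  }
  if (length(sample_ids) == nrow(X)) rownames(X) <- sample_ids
  if (is.null(colnames(X)) && nrow(snp_map) == ncol(X)) {
    colnames(X) <- snp_map$snp_id
  }
  if (!is.null(y)) y <- as.integer(y)
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    # freeze categorical levels so every subset one-hot expands identically
    covariates <- dplyr::mutate(covariates,
                                dplyr::across(dplyr::where(is.character), factor))
  }
  obj <- structure(
    list(X = X, snp_map = snp_map, y = y, covariates = covariates,
         sample_ids = as.character(sample_ids)),
    class = "genotype_dataset"
  )
  validate_genotype_dataset(obj)
  obj
}

validate_genotype_dataset <- function(data) {
  X <- data$X
  if (ncol(X) != nrow(data$snp_map)) {
    abort(sprintf("snp_map has %d rows but X has %d columns",
                  nrow(data$snp_map), ncol(X)))
  }
  if (!all(c("snp_id", "chrom", "pos") %in% names(data$snp_map))) {
    abort("snp_map must have columns snp_id, chrom, pos")
  }
  chrom <- data$snp_map$chrom
  if (length(chrom) && (!is.numeric(chrom) || any(chrom < 1 | chrom > 22))) {
    abort("chromosomes must be autosomes 1-22")
  }
  vals <- X[!is.na(X)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    abort("non-missing genotype codes must be 0, 1 or 2")
  }
  if (!is.null(data$y)) {
    if (length(data$y) != nrow(X)) abort("y must have one label per sample")
    if (!all(data$y %in% c(0L, 1L))) abort("labels must be 0 or 1")
  }
  if (!is.null(data$covariates) && nrow(data$covariates) != nrow(X)) {
    abort("covariates must have one row per sample")
  }
  if (length(data$sample_ids) != nrow(X)) {
    abort("sample_ids must have one entry per sample")
  }
  invisible(data)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset> %d samples x %d SNPs (%d chromosome%s)\n",
              nrow(x$X), ncol(x$X), length(unique(x$snp_map$chrom)),
              if (length(unique(x$snp_map$chrom)) == 1) "" else "s"))
  if (!is.null(x$y)) {
    cat(sprintf("  labels: %d class 0 / %d class 1\n",
                sum(x$y == 0L), sum(x$y == 1L)))
  }
  if (!is.null(x$covariates)) {
    cat(sprintf("  covariates: %s\n", paste(names(x$covariates), collapse = ", ")))
  }
  n_miss <- sum(is.na(x$X))
  if (n_miss > 0) cat(sprintf("  missing genotypes: %d\n", n_miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$X)

#' Subset a genotype dataset by samples and/or SNP columns
#'
#' @param data A [genotype_dataset()].
#' @param samples Integer/logical index of samples to keep.
#' @param snps Integer/logical index of SNP columns to keep.
#' @return A `genotype_dataset` restricted to the requested rows/columns.
#' @export
subset_dataset <- function(data, samples = NULL, snps = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(data$X))
  if (is.null(snps)) snps <- seq_len(ncol(data$X))
  genotype_dataset(
    X = data$X[samples, snps, drop = FALSE],
    snp_map = data$snp_map[snps, , drop = FALSE],
    y = data$y[samples],
    covariates = if (!is.null(data$covariates)) data$covariates[samples, , drop = FALSE],
    sample_ids = data$sample_ids[samples]
  )
}

#' Encode allele-pair genotype calls as additive minor-allele counts
#'
#' Homozygous major, heterozygous and homozygous minor genotypes map to 0, 1
#' and 2 — the count of minor alleles — assuming additive allele effects.
#' Encoding is idempotent: numeric input already in `{0, 1, 2, NA}` is
#' returned unchanged.
#'
#' @param calls Character vector of genotype calls, each a pair of alleles
#'   over `{A, C, G, T}` written as e.g. `"AT"`, `"A/T"` or `"A|T"`; `NA`
#'   for missing. Numeric vectors already coded 0/1/2 pass through.
#' @param minor_allele Single character: the dataset's minor allele at this
#'   SNP.
#' @param ref_allele Optional single character: the major (reference) allele.
#'   When supplied, any call carrying an allele outside
#'   `{ref_allele, minor_allele}` raises a malformed-call error.
#' @param snp_id Optional SNP name used in error messages.
#' @return Numeric vector of minor-allele counts in `{0, 1, 2}`, `NA` where
#'   the call was missing.
#' @examples
#' encode_genotype(c("AA", "A/T", "TT", NA), minor_allele = "T")
#' @export
encode_genotype <- function(calls, minor_allele, ref_allele = NULL,
                            snp_id = NULL) {
  if (is.numeric(calls)) {
    bad <- !is.na(calls) & !(calls %in% c(0, 1, 2))
    if (any(bad)) abort("numeric calls must already be coded 0/1/2")
    return(as.double(calls))
  }
  calls <- as.character(calls)
  out <- rep(NA_real_, length(calls))
  ok <- !is.na(calls) & calls != "." & calls != "./."
  alleles <- gsub("[/|]", "", calls[ok])
  if (any(nchar(alleles) != 2L)) {
    abort("each genotype call must be a pair of alleles")
  }
  a1 <- substr(alleles, 1, 1)
  a2 <- substr(alleles, 2, 2)
  if (!all(c(a1, a2) %in% c("A", "C", "G", "T"))) {
    abort("alleles must be one of A, C, G, T")
  }
  if (!is.null(ref_allele)) {
    allowed <- c(ref_allele, minor_allele)
    bad <- !(a1 %in% allowed) | !(a2 %in% allowed)
    if (any(bad)) {
      abort(sprintf(
        "malformed call%s: allele outside {%s}",
        if (is.null(snp_id)) "" else paste0(" at SNP ", snp_id),
        paste(allowed, collapse = ", ")
      ))
    }
  }
  out[ok] <- (a1 == minor_allele) + (a2 == minor_allele)
  out
}

#' Build the numeric design view used by the pipeline
#'
#' Returns the analysis matrix for one chromosome (or the whole genome):
#' SNP dosage columns, optionally followed by numerically-coded covariate
#' columns (binary/ordinal variables as their codes, categorical variables
#' one-hot expanded). A `feature_info` tibble describes every column.
#'
#' @param data A [genotype_dataset()] with labels.
#' @param chrom Optional single chromosome to restrict the SNP columns to.
#' @param include_covariates Append covariate columns (default `TRUE` when
#'   covariates are present).
#' @return A list of class `dataset_view` with elements `X` (numeric
#'   matrix), `y`, `feature_info` (tibble: `feature`, `is_snp`, `snp_id`,
#'   `chrom`, `pos`) and `sample_ids`.
#' @export
dataset_view <- function(data, chrom = NULL,
                         include_covariates = !is.null(data$covariates)) {
  keep <- if (is.null(chrom)) seq_len(ncol(data$X)) else which(data$snp_map$chrom == chrom)
  X <- data$X[, keep, drop = FALSE]
  info <- tibble::tibble(
    feature = colnames(X) %||% data$snp_map$snp_id[keep],
    is_snp = TRUE,
    snp_id = data$snp_map$snp_id[keep],
    chrom = as.integer(data$snp_map$chrom[keep]),
    pos = as.integer(data$snp_map$pos[keep])
  )
  colnames(X) <- info$feature
  if (include_covariates && !is.null(data$covariates) && ncol(data$covariates) > 0) {
    C <- covariate_matrix(data$covariates)
    X <- cbind(X, C)
    info <- dplyr::bind_rows(info, tibble::tibble(
      feature = colnames(C), is_snp = FALSE,
      snp_id = NA_character_, chrom = NA_integer_, pos = NA_integer_
    ))
  }
  structure(
    list(X = X, y = data$y, feature_info = info, sample_ids = data$sample_ids),
    class = "dataset_view"
  )
}

# numeric coding of the covariate table: numerics pass through, two-level
# factors/characters become 0/1, >2-level ones are one-hot expanded
covariate_matrix <- function(covariates) {
  cols <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      m <- matrix(as.double(v), ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- if (is.factor(v)) v else factor(v)
      if (nlevels(f) <= 2) {
        m <- matrix(as.double(as.integer(f) - 1L), ncol = 1,
                    dimnames = list(NULL, nm))
      } else {
        m <- sapply(levels(f), function(l) as.double(f == l))
        colnames(m) <- paste0(nm, "_", levels(f))
      }
    }
    m
  })
  do.call(cbind, cols)
}

#' @export
print.dataset_view <- function(x, ...) {
  cat(sprintf("<dataset_view> %d samples x %d features (%d SNPs, %d covariate columns)\n",
              nrow(x$X), ncol(x$X), sum(x$feature_info$is_snp),
              sum(!x$feature_info$is_snp)))
  invisible(x)
}
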