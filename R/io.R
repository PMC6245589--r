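#' Read a genotype dataset from disk
#'
#' Two formats are supported. `"dosage"` reads a plain additive-dosage TSV
#' (header row of SNP ids, first column the sample id, cells in
#' `{0, 1, 2, NA}`) together with a SNP-map TSV (`snp_id`, `chrom`, `pos`).
#' `"vcf"` reads a VCF 4.x file, maps diploid GT fields to minor-allele
#' counts (the minor allele is the lower-frequency allele across the file,
#' ties broken toward ALT) and drops non-autosomal records with a message.
#'
#' @param path Path to the dosage TSV or VCF file.
#' @param format `"dosage"` or `"vcf"`.
#' @param snp_map Path to the SNP-map TSV (required for `"dosage"`).
#' @param covariates Optional path to a covariate TSV keyed by sample id
#'   (first column).
#' @param labels Optional path to a two-column TSV (`sample_id`, `y`).
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("dosage", "vcf"), snp_map = NULL,
                           covariates = NULL, labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("input path does not exist: %s", path))
  data <- switch(format,
    dosage = read_dosage(path, snp_map),
    vcf = read_vcf_genotypes(path)
  )
  if (!is.null(covariates)) {
    cov <- readr::read_tsv(covariates, show_col_types = FALSE)
    idx <- match(data$sample_ids, cov[[1]])
    if (anyNA(idx)) abort("covariate table is missing some samples")
    data$covariates <- tibble::as_tibble(cov[idx, -1, drop = FALSE])
  }
  if (!is.null(labels)) {
    lab <- readr::read_tsv(labels, show_col_types = FALSE)
    idx <- match(data$sample_ids, lab[[1]])
    if (anyNA(idx)) abort("label table is missing some samples")
    data$y <- as.integer(lab[[2]][idx])
  }
  validate_genotype_dataset(data)
  data
}

read_dosage <- function(path, snp_map) {
  if (is.null(snp_map)) abort("dosage format needs a snp_map TSV")
  dosage <- readr::read_tsv(path, show_col_types = FALSE)
  map <- readr::read_tsv(snp_map, show_col_types = FALSE)
  sample_ids <- as.character(dosage[[1]])
  X <- as.matrix(dosage[, -1, drop = FALSE])
  bad <- which(!is.na(X) & !(X %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("unparseable dosage value at data line %d (SNP %s)",
                  bad[1, 1], colnames(X)[bad[1, 2]]))
  }
  idx <- match(colnames(X), map$snp_id)
  if (anyNA(idx)) abort("snp_map is missing some SNP ids from the dosage file")
  map <- map[idx, , drop = FALSE]
  n_before <- nrow(map)
  auto <- !is.na(suppressWarnings(as.integer(map$chrom))) &
    suppressWarnings(as.integer(map$chrom)) %in% 1:22
  if (any(!auto)) {
    message(sprintf("dropped %d non-autosomal SNP(s)", sum(!auto)))
  }
  map$chrom <- suppressWarnings(as.integer(map$chrom))
  genotype_dataset(X[, auto, drop = FALSE], map[auto, , drop = FALSE],
                   sample_ids = sample_ids)
}

read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fm <- vcfR::getFIX(vcf)
  if (is.null(dim(fm))) fm <- t(fm)  # single-record files come back as a vector
  fix <- tibble::as_tibble(as.data.frame(fm))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- t(gt)
  if (any(grepl(",", fix$ALT))) {
    abort("multi-allelic sites are not supported; split or drop them first")
  }
  ploidy_tokens <- unique(nchar(gsub("[^/|]", "", gt[!is.na(gt)])))
  if (length(ploidy_tokens) > 1) abort("mixed ploidy in VCF GT fields")
  chrom_int <- suppressWarnings(as.integer(gsub("^chr", "", fix$CHROM)))
  auto <- !is.na(chrom_int) & chrom_int %in% 1:22
  if (any(!auto)) message(sprintf("dropped %d non-autosomal record(s)", sum(!auto)))
  fix <- fix[auto, , drop = FALSE]
  gt <- gt[auto, , drop = FALSE]
  chrom_int <- chrom_int[auto]
  # ALT-allele dosage from GT indices, then orient to the minor allele
  alt_count <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    toks <- strsplit(g, "[/|]")[[1]]
    if (any(toks == ".")) return(NA_real_)
    sum(toks != "0")
  }
  D <- matrix(vapply(gt, alt_count, numeric(1)), nrow(gt), ncol(gt),
              dimnames = dimnames(gt))
  alt_freq <- rowMeans(D, na.rm = TRUE) / 2
  minor_is_alt <- alt_freq <= 0.5  # ties toward ALT
  Xs <- t(ifelse(matrix(minor_is_alt, nrow(D), ncol(D)), D, 2 - D))
  snp_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                   paste0(fix$CHROM, ":", fix$POS), fix$ID)
  map <- tibble::tibble(
    snp_id = snp_id,
    chrom = chrom_int,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    minor = unname(ifelse(minor_is_alt, fix$ALT, fix$REF))
  )
  colnames(Xs) <- snp_id
  genotype_dataset(Xs, map, sample_ids = colnames(gt))
}

#' Write a genotype dataset as plain-text TSV files
#'
#' Writes `<prefix>_dosage.tsv`, `<prefix>_snps.tsv` and, when present,
#' `<prefix>_covariates.tsv` and `<prefix>_labels.tsv`. The files round-trip
#' through [read_genotypes()].
#'
#' @param data A [genotype_dataset()].
#' @param prefix Path prefix for the output files.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_genotypes <- function(data, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- c(dosage = paste0(prefix, "_dosage.tsv"),
             snps = paste0(prefix, "_snps.tsv"))
  dosage <- tibble::as_tibble(data$X)
  dosage <- dplyr::bind_cols(tibble::tibble(sample_id = data$sample_ids), dosage)
  readr::write_tsv(dosage, paths[["dosage"]])
  readr::write_tsv(data$snp_map, paths[["snps"]])
  if (!is.null(data$covariates)) {
    paths[["covariates"]] <- paste0(prefix, "_covariates.tsv")
    readr::write_tsv(
      dplyr::bind_cols(tibble::tibble(sample_id = data$sample_ids),
                       data$covariates),
      paths[["covariates"]]
    )
  }
  if (!is.null(data$y)) {
    paths[["labels"]] <- paste0(prefix, "_labels.tsv")
    readr::write_tsv(tibble::tibble(sample_id = data$sample_ids, y = data$y),
                     paths[["labels"]])
  }
  invisible(paths)
}
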