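test_that("additive encoding counts minor alleles", {
  expect_identical(encode_genotype("AA", minor_allele = "T"), 0)
  expect_identical(encode_genotype("A/T", minor_allele = "T"), 1)
  expect_identical(encode_genotype("TT", minor_allele = "T"), 2)
  expect_identical(
    encode_genotype(c("AA", "A|T", "TT", NA), minor_allele = "T"),
    c(0, 1, 2, NA)
  )
})

test_that("encoding is idempotent on already-coded input", {
  codes <- c(0, 1, 2, NA, 2)
  expect_identical(encode_genotype(codes, minor_allele = "T"), codes)
  expect_error(encode_genotype(c(0, 3), minor_allele = "T"), "0/1/2")
})

test_that("malformed calls are rejected when the allele pair is declared", {
  expect_error(
    encode_genotype("AC", minor_allele = "T", ref_allele = "A",
                    snp_id = "rs42"),
    "malformed call.*rs42"
  )
  expect_error(encode_genotype("A", minor_allele = "T"), "pair")
  expect_error(encode_genotype("AN", minor_allele = "T"), "A, C, G, T")
})

test_that("the container enforces its invariants", {
  map <- tibble::tibble(snp_id = c("a", "b"), chrom = c(1L, 2L),
                        pos = c(100L, 200L))
  X <- matrix(c(0, 1, 2, 0), 2, 2)
  d <- genotype_dataset(X, map, y = c(0L, 1L))
  expect_s3_class(d, "genotype_dataset")
  expect_identical(dim(d), c(2L, 2L))

  expect_error(genotype_dataset(matrix(3, 1, 1), map[1, ]), "0, 1 or 2")
  expect_error(
    genotype_dataset(X, dplyr::mutate(map, chrom = c(1L, 23L))),
    "autosomes"
  )
  expect_error(genotype_dataset(X, map[1, ]), "columns")
  expect_error(genotype_dataset(X, map, y = c(0L, 1L, 0L)), "one label")
})

test_that("dataset_view restricts to a chromosome and expands covariates", {
  cov <- tibble::tibble(age = c(61, 55, 70),
                        histology = c("ADC", "SCC", "LCC"))
  map <- tibble::tibble(snp_id = c("a", "b", "c"), chrom = c(1L, 1L, 2L),
                        pos = c(1L, 2L, 3L))
  d <- genotype_dataset(matrix(rep(0:2, 3), 3, 3), map,
                        y = c(0L, 1L, 0L), covariates = cov)
  v <- dataset_view(d, chrom = 1)
  expect_true(all(v$feature_info$chrom[v$feature_info$is_snp] == 1))
  expect_setequal(
    v$feature_info$feature[!v$feature_info$is_snp],
    c("age", "histology_ADC", "histology_LCC", "histology_SCC")
  )
  expect_equal(nrow(v$X), 3)
  # one-hot columns are indicator-coded
  expect_equal(sum(v$X[, "histology_ADC"]), 1)

  v2 <- dataset_view(d, chrom = 1, include_covariates = FALSE)
  expect_equal(ncol(v2$X), 2)
})

test_that("subsetting preserves categorical covariate levels", {
  cov <- tibble::tibble(histology = c("ADC", "SCC", "LCC", "ADC"))
  map <- tibble::tibble(snp_id = "a", chrom = 1L, pos = 1L)
  d <- genotype_dataset(matrix(0:1, 4, 1), map, y = c(0L, 1L, 0L, 1L),
                        covariates = cov)
  sub <- subset_dataset(d, samples = c(1, 4))  # no SCC or LCC rows left
  expect_identical(colnames(snpstab:::covariate_matrix(sub$covariates)),
                   colnames(snpstab:::covariate_matrix(d$covariates)))
})
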