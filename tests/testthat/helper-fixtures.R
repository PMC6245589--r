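# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

# minimal labelled dataset: n0/n1 class counts, m SNPs on the given
# chromosomes, genotypes drawn iid Binomial(2, maf)
make_dataset <- function(n0 = 20, n1 = 10, m = 8, chrom = 1, maf = 0.3,
                         seed = 42, covariates = NULL) {
  n <- n0 + n1
  set.seed(seed)
  X <- matrix(rbinom(n * m, 2, maf), n, m)
  chroms <- rep_len(chrom, m)
  map <- tibble::tibble(
    snp_id = sprintf("rs%03d", seq_len(m)),
    chrom = chroms,
    pos = as.integer(seq_len(m) * 1000 + chroms)
  )
  genotype_dataset(X, map, y = c(rep(0L, n0), rep(1L, n1)),
                   covariates = covariates)
}

# cohort matching the emulated study arithmetic: 178 samples, 137/41 classes
make_cohort_178 <- function(m = 6, seed = 7) {
  make_dataset(n0 = 137, n1 = 41, m = m, seed = seed)
}

# a toy GWAS-catalog association TSV; returns the path and the record tibble
write_toy_catalog <- function(path = tempfile(fileext = ".tsv")) {
  set.seed(99)
  n <- 44
  tbl <- tibble::tibble(
    CHR_ID = as.character(sample(1:5, n, replace = TRUE)),
    CHR_POS = as.character(sample(1e5:2e5, n)),
    SNPS = sprintf("rs%05d", sample(1e4, n)),
    `DISEASE/TRAIT` = sample(c("Lung cancer", "Breast cancer", "Height",
                               "Pulmonary function", "Type 2 diabetes"),
                             n, replace = TRUE),
    `P-VALUE` = formatC(10^-runif(n, 6.1, 12), format = "e")
  )
  # 2 duplicated (chrom, pos, trait) triples, 2 interaction rows, 1 bad
  # position, 1 p-value above threshold: 50 rows total
  extra <- tbl[1:2, ]
  inter <- tibble::tibble(
    CHR_ID = c("1", "2"), CHR_POS = c("123456", "234567"),
    SNPS = c("rs1 x rs2", "rs3; rs4"),
    `DISEASE/TRAIT` = c("Lung cancer", "Height"),
    `P-VALUE` = c("1e-9", "1e-10")
  )
  bad_pos <- tibble::tibble(CHR_ID = "3", CHR_POS = "??", SNPS = "rs77777",
                            `DISEASE/TRAIT` = "Lung cancer",
                            `P-VALUE` = "1e-9")
  weak <- tibble::tibble(CHR_ID = "4", CHR_POS = "150000", SNPS = "rs88888",
                         `DISEASE/TRAIT` = "Lung cancer",
                         `P-VALUE` = "1e-5")
  out <- dplyr::bind_rows(tbl, extra, inter, bad_pos, weak)
  readr::write_tsv(out, path)
  list(path = path, records = out)
}

# independent brute-force stability count: reimplements
# impute -> variance filter -> standardize -> ANOVA top-k -> count, without
# calling any pipeline internals
brute_force_anova_scores <- function(X, y, subsamples, keep_fraction) {
  score <- integer(ncol(X))
  for (idx in subsamples) {
    Xs <- X[idx, , drop = FALSE]
    ys <- y[idx]
    for (j in seq_len(ncol(Xs))) {
      cm <- mean(Xs[, j], na.rm = TRUE)
      Xs[is.na(Xs[, j]), j] <- cm
    }
    keep <- apply(Xs, 2, function(v) stats::var(v) > 0)
    Z <- scale(Xs[, keep, drop = FALSE])
    p <- apply(Z, 2, function(v) {
      stats::anova(stats::lm(v ~ factor(ys)))$`Pr(>F)`[1]
    })
    k <- ceiling(keep_fraction * sum(keep))
    sel_kept <- order(p, seq_along(p))[seq_len(k)]
    sel <- which(keep)[sel_kept]
    score[sel] <- score[sel] + 1L
  }
  score
}

# fraction-free access to a tiny planted-signal cohort shared by tests
signal_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(
        n_samples = 400,
        n_snps_per_chromosome = c(rep(30, 3), rep(0, 19)),
        maf_range = c(0.2, 0.4),
        causal_snps = tibble::tibble(chrom = c(1, 1, 2, 2, 3, 3),
                                     index = c(5, 20, 8, 12, 3, 20),
                                     beta = log(3)),
        class_fraction = 0.3, with_covariates = FALSE, seed = 202
      )
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})
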