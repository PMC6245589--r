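#' Configuration for the synthetic genotype cohort generator
#'
#' Defaults emulate the study conditions the framework targets: a cohort of
#' 178 patients with a 137/41 responder/non-responder imbalance, 22
#' autosomes, per-SNP minor-allele frequencies of at least 0.01, clinical
#' covariates with the marginal frequencies of a first-line platinum-treated
#' NSCLC cohort, and a small set of planted causal SNPs acting through a
#' logistic model. The per-chromosome SNP count defaults to 200 — enough to
#' exercise chromosome-wise selection while keeping a desk-scale cohort.
#'
#' @param n_samples Cohort size (default 178).
#' @param n_snps_per_chromosome Integer vector of length 22 (or a scalar,
#'   recycled) giving SNP counts per autosome (default 200 each).
#' @param maf_range Range minor-allele frequencies are drawn from uniformly
#'   (default `c(0.01, 0.5)`).
#' @param ld_block_size SNPs per linkage-disequilibrium block (default 1 =
#'   independent SNPs).
#' @param ld_rho Latent-Gaussian correlation within an LD block (default 0).
#' @param causal_snps Data frame with columns `chrom`, `index` (SNP index
#'   within the chromosome) and `beta` (per-minor-allele log-odds); `NULL`
#'   for a null cohort.
#' @param intercept Logistic intercept; `NULL` (default) auto-calibrates it
#'   by bisection so the realized class-1 fraction matches
#'   `class_fraction`.
#' @param covariate_effects Named numeric vector of log-odds per unit of a
#'   numerically-coded covariate column (default none).
#' @param class_fraction Target class-1 (non-responder) fraction
#'   (default 41/178).
#' @param missing_rate Fraction of genotype entries set missing to exercise
#'   imputation (default 0).
#' @param with_covariates Simulate the clinical covariate table
#'   (default `TRUE`).
#' @param seed Master seed for the generator.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 178,
                              n_snps_per_chromosome = 200,
                              maf_range = c(0.01, 0.5),
                              ld_block_size = 1,
                              ld_rho = 0,
                              causal_snps = NULL,
                              intercept = NULL,
                              covariate_effects = NULL,
                              class_fraction = 41 / 178,
                              missing_rate = 0,
                              with_covariates = TRUE,
                              seed = 1) {
  if (length(n_snps_per_chromosome) == 1) {
    n_snps_per_chromosome <- rep(as.integer(n_snps_per_chromosome), 22)
  }
  if (length(n_snps_per_chromosome) != 22) {
    abort("n_snps_per_chromosome must have length 1 or 22")
  }
  if (maf_range[1] < 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    abort("maf_range must be an increasing range within [0, 0.5]")
  }
  if (class_fraction <= 0 || class_fraction >= 1) {
    abort("class_fraction must lie strictly between 0 and 1")
  }
  if (any(n_snps_per_chromosome > 0) &&
      ld_block_size > min(n_snps_per_chromosome[n_snps_per_chromosome > 0])) {
    abort("ld_block_size exceeds the smallest chromosome's SNP count")
  }
  if (!is.null(causal_snps)) {
    causal_snps <- tibble::as_tibble(causal_snps)
    stopifnot(all(c("chrom", "index", "beta") %in% names(causal_snps)))
    bad <- causal_snps$index > n_snps_per_chromosome[causal_snps$chrom]
    if (any(bad)) abort("causal SNP index exceeds its chromosome's SNP count")
  }
  structure(
    list(n_samples = as.integer(n_samples),
         n_snps_per_chromosome = as.integer(n_snps_per_chromosome),
         maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
         ld_rho = ld_rho, causal_snps = causal_snps, intercept = intercept,
         covariate_effects = covariate_effects,
         class_fraction = class_fraction, missing_rate = missing_rate,
         with_covariates = isTRUE(with_covariates), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate additively-coded genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP draws a minor-allele frequency uniformly from `maf_range` and its
#' codes are the sum of two allele indicators. Within an LD block the two
#' allele draws of every SNP share a latent Gaussian factor with correlation
#' `ld_rho`, thresholded at the normal quantile of the SNP's MAF, so the
#' marginal distribution stays Binomial(2, MAF) while neighbouring SNPs are
#' correlated.
#'
#' @param config A [simulation_config()].
#' @return A [genotype_dataset()] without labels (covariates attached when
#'   requested by the config).
#' @export
simulate_genotypes <- function(config) {
  n <- config$n_samples
  maps <- list()
  blocks <- list()
  with_seed(child_seed(config$seed, 101), {
    for (chr in 1:22) {
      m <- config$n_snps_per_chromosome[chr]
      if (m == 0) next
      maf <- runif(m, config$maf_range[1], config$maf_range[2])
      Xc <- matrix(0, n, m)
      starts <- seq(1, m, by = config$ld_block_size)
      for (s in starts) {
        cols <- s:min(s + config$ld_block_size - 1L, m)
        Xc[, cols] <- simulate_ld_block(n, maf[cols], config$ld_rho)
      }
      pos <- sort(sample.int(250e6, m))
      maps[[chr]] <- tibble::tibble(
        snp_id = sprintf("chr%d_snp%d", chr, seq_len(m)),
        chrom = chr, pos = pos, maf = maf
      )
      blocks[[chr]] <- Xc
    }
  })
  X <- do.call(cbind, blocks)
  map <- dplyr::bind_rows(maps)
  colnames(X) <- map$snp_id
  if (config$missing_rate > 0) {
    with_seed(child_seed(config$seed, 102), {
      drop <- runif(length(X)) < config$missing_rate
      X[drop] <- NA_real_
    })
  }
  covariates <- if (config$with_covariates) {
    simulate_covariates(n, child_seed(config$seed, 103))
  }
  genotype_dataset(X, map, covariates = covariates,
                   sample_ids = sprintf("S%04d", seq_len(n)))
}

# one LD block: two latent allele draws per sample sharing a block factor
simulate_ld_block <- function(n, maf, rho) {
  m <- length(maf)
  draw_alleles <- function() {
    if (rho > 0 && m > 1) {
      f <- rnorm(n)
      z <- sqrt(rho) * matrix(f, n, m) + sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
    } else {
      z <- matrix(rnorm(n * m), n, m)
    }
    # threshold at qnorm(maf): indicator of carrying the minor allele
    sweep(z, 2, qnorm(maf), `<`) + 0
  }
  draw_alleles() + draw_alleles()
}

# clinical covariate table with the marginal frequencies of the emulated
# cohort: gender, smoker, ECOG performance status, histology, treatment, arm
simulate_covariates <- function(n, seed) {
  with_seed(seed, tibble::tibble(
    gender = rbinom(n, 1, 0.22),                        # 1 = female
    smoker = rbinom(n, 1, 0.94),                        # 1 = smoker
    ecog = sample(0:2, n, replace = TRUE, prob = c(0.33, 0.66, 0.01)),
    histology = sample(c("ADC", "SCC", "LCC", "other"), n, replace = TRUE,
                       prob = c(0.56, 0.36, 0.05, 0.03)),
    treatment = sample(c("doce_cis", "gemci_cis", "doce"), n, replace = TRUE,
                       prob = c(0.69, 0.25, 0.06)),
    arm = rbinom(n, 1, 0.47)                            # 1 = biomarker-directed
  ))
}

#' Simulate the binary response through a logistic model
#'
#' Class probabilities are `plogis(b0 + sum(beta * code) + covariate
#' terms)`. With `intercept = NULL` the intercept is calibrated by bisection
#' against the realized labels: a single vector of uniforms is drawn and
#' `y = 1{u < p(b0)}`, whose class-1 count is monotone in `b0`, so bisection
#' lands the realized class-1 count on the target (within one sample) while
#' preserving the genetic and covariate effects.
#'
#' @param data A [genotype_dataset()] from [simulate_genotypes()].
#' @param config The same [simulation_config()].
#' @return `data` with the `y` labels filled in; the calibrated intercept is
#'   stored in `attr(data, "intercept")`.
#' @export
simulate_phenotype <- function(data, config) {
  n <- nrow(data$X)
  eta <- rep(0, n)
  if (!is.null(config$causal_snps)) {
    for (i in seq_len(nrow(config$causal_snps))) {
      cs <- config$causal_snps[i, ]
      col <- which(data$snp_map$chrom == cs$chrom)[cs$index]
      if (is.na(col)) abort("causal SNP index not present in dataset")
      g <- data$X[, col]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      eta <- eta + cs$beta * g
    }
  }
  if (!is.null(config$covariate_effects)) {
    C <- covariate_matrix(data$covariates)
    for (nm in names(config$covariate_effects)) {
      if (!nm %in% colnames(C)) abort(sprintf("unknown covariate effect: %s", nm))
      eta <- eta + config$covariate_effects[[nm]] * C[, nm]
    }
  }
  u <- with_seed(child_seed(config$seed, 104), runif(n))
  target <- as.integer(round_half_away(config$class_fraction * n))
  if (is.null(config$intercept)) {
    count_at <- function(b0) sum(u < plogis(b0 + eta))
    lo <- -40; hi <- 40
    if (count_at(lo) > target || count_at(hi) < target) {
      abort("target class fraction unattainable by intercept calibration")
    }
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (count_at(mid) < target) lo <- mid else hi <- mid
    }
    b0 <- hi
    realized <- count_at(b0) / n
    if (abs(realized - config$class_fraction) > 0.02 + 1 / n) {
      abort("intercept calibration failed to reach the target class fraction")
    }
  } else {
    b0 <- config$intercept
  }
  data$y <- as.integer(u < plogis(b0 + eta))
  attr(data, "intercept") <- b0
  data
}

#' Simulate a complete labelled cohort
#'
#' Convenience wrapper: [simulate_genotypes()] then [simulate_phenotype()].
#'
#' @param config A [simulation_config()].
#' @return A labelled [genotype_dataset()].
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_samples = 60,
#'   n_snps_per_chromosome = 5, seed = 7))
#' table(cohort$y)
#' @export
simulate_cohort <- function(config) {
  simulate_phenotype(simulate_genotypes(config), config)
}
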