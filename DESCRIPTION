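Package: snpstab
Title: Chromosome-Partitioned Stability Selection for SNP-Based
    Classification of Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A leakage-safe machine-learning framework for classifying a
    binary clinical response from large-scale SNP genotype data. Genotypes
    are additively encoded (0/1/2 minor-allele counts) and analysed per
    chromosome with a six-stage pipeline (mean imputation, variance filter,
    standardization, feature selection, class-imbalance resampling inside
    cross-validation folds, classification) tuned by stratified 5-fold
    grid search on weighted F1. Feature stability is scored by refitting
    each chromosome's tuned pipeline on repeated subsamples of an
    independent stability set; features passing a stability threshold are
    merged across chromosomes into a final genome-wide model. Includes a
    synthetic genotype cohort generator (Hardy-Weinberg sampling, optional
    LD blocks, planted causal SNPs under a logistic model), per-classifier
    feature ranking with effect signs, tabular experiment reports, and
    intersection of selected SNPs with GWAS Catalog associations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
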