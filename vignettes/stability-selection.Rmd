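---
title: "Chromosome-partitioned stability selection for SNP-based response classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome-partitioned stability selection for SNP-based response classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpstab)
```

## The problem

Pharmacogenomic cohorts pair genome-wide SNP genotypes with a binary
clinical outcome — here, response to first-line platinum-based chemotherapy
in advanced non-small-cell lung cancer, dichotomised from RECIST categories
into responders (class 0) and non-responders (class 1). Three features of
such data defeat naive supervised learning: the feature count (10^5–10^7
SNPs) dwarfs the cohort (around 178 patients), the classes are heavily
imbalanced (roughly 137:41), and any preprocessing fitted on the full data
before cross-validation leaks information and inflates every score.

`snpstab` implements a framework that addresses all three at once:

1. **A six-stage pipeline**, fitted *entirely inside* every
   cross-validation fold: mean imputation of missing genotype codes, a
   zero-variance filter, standardization to zero mean and unit variance,
   feature selection, class-imbalance resampling (training folds only), and
   a classifier. Pipelines are tuned by stratified 5-fold grid search with
   the class-support-weighted F1 as scoring function.
2. **Chromosome partitioning with stability scoring.** The genome is
   analysed one autosome at a time ("partial analysis"), so each model fit
   touches only a tractable slice. The tuned per-chromosome pipeline is
   then refitted on `S` subsamples (each a stratified draw of `T` percent,
   without replacement) of an *independent stability set*; a feature's
   stability score counts the refits whose feature-selection support
   retained it, so scores range over `[0, S]`.
3. **Merge and final model.** Features scoring at least a threshold `W` in
   their chromosome are merged across the genome, and the same pipeline
   instantiation is re-tuned on the merged training view, giving one final
   model that can exploit SNPs from all chromosomes. It is evaluated once
   on a held-out test set that no fitting step ever saw, and whose class
   distribution is never resampled.

The stage menus — feature selection in {ANOVA filter, recursive feature
elimination with L1 logistic regression (RFE-LR), embedded L1 logistic
regression (RLR-L1)}, sampling in {none, down, up, SMOTE}, classifier in
{linear SVM, random forest, k-nearest neighbours} — define a 3 × 4 × 3 grid
of 36 experiments, each running the full chain.

## Data model and encoding

Genotypes are additively encoded: each SNP is the count of minor alleles,
0 (homozygous major), 1 (heterozygous) or 2 (homozygous minor), assuming
allele effects add. Only autosomes 1–22 are analysed; multi-allelic sites
are rejected rather than guessed at. For VCF input the minor allele is
defined per dataset as the lower-frequency allele over the whole file, ties
broken toward the ALT allele; positions are 1-based as in VCF. Clinical
covariates (gender, smoking status, ECOG performance status, histology,
treatment, trial arm) ride along as numeric or one-hot-expanded columns;
by default they enter both the per-chromosome and the final analyses, and
they pass through the same variance filter as SNPs.

## Splits

The cohort is split 20% / 80% into test and "preliminary" sets, and the
preliminary set 50% / 50% into training and stability sets, all stratified
by class. Part sizes are the requested fraction rounded half away from
zero; the per-class allocation rounds proportional shares the same way with
a largest-remainder correction so totals are exact. On 178 samples
(137/41) this reproduces 36 test samples (8 of class 1) and 71 + 71
training/stability samples. The stability set exists so that the stability
filter — which does peek at data outside the final CV loop — at least never
peeks at training or test samples; the residual model-selection bias this
leaves is documented, not corrected (no nested outer CV).

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 5 | CV folds (stratified, seeded) |
| scoring | weighted F1 | class-support-weighted mean of per-class F1 = 2PR/(P+R) |
| `S` | 100 | stability subsample refits per chromosome |
| `T` | 0.8 | fraction of the stability set drawn per refit, stratified, without replacement |
| `W` | 100 | stability threshold for the merge; `W = S` keeps only features selected in every refit |
| partial FS budget | 2% | fraction of a chromosome's variables kept (RFE step 4% of the current set per round) |
| final FS budget | 10% of the *total* variable count | see below |
| SVM cost | 10^-3 … 10^3 | grid-searched |
| RF trees | 30 … 2999 | grid-searched |
| KNN neighbours | 5, 20, 35, 50 | grid-searched |
| RLR-L1 `C` | 100 … 10000 | inverse regularization, grid-searched; keep threshold 10^-10 on the absolute coefficient |

Two readings of the final-analysis selection budget are possible: a
percentage of the merged view's width, or a percentage of the study's total
variable count. We implement the latter. A stability-thresholded merge is
orders of magnitude smaller than 10% of a genome-wide input, so under this
reading the final selection step retains the whole merged set — which is
what reported per-pipeline "relevant feature" counts look like (identical
sets across sampling methods, equal to the merged set). Under the former
reading the final model would be throttled to a handful of features
whenever the merge is small, discarding most of the stable signal the
framework just worked to find. The budget only binds when a merge is
unusually large relative to the input.

Grid-search ties are broken by declared grid order. Stability refits reuse
the partial model's best hyper-parameters frozen (they are *re-fitted*, not
re-tuned; re-tuning would multiply cost by `S` for no stated benefit).
SMOTE uses 5 nearest minority neighbours, reduced to `minority − 1` when
the minority class is smaller; synthetic points are uniform draws on the
segment between a minority sample and one of its neighbours, in the
standardized selected-feature space. L1 logistic regressions map the
inverse-regularization convention `C` to a coordinate-descent penalty
`lambda = 1/(n·C)`.

One deliberate deviation: a summary-table footnote in the source material
defines F1 as `P·R/(P+R)`; we use the standard `2PR/(P+R)`, consistent with
the weighted-F1 scoring function used everywhere else.

## The synthetic cohort generator

No patient-level data from the motivating study is available, so the
package ships a generator that emulates its statistical shape and makes
every stage testable:

* **Genotypes**: each SNP draws a minor-allele frequency uniformly from
  `[0.01, 0.5]` and samples codes as the sum of two allele indicators
  (Hardy–Weinberg). Within an optional LD block the allele draws share a
  latent Gaussian factor with correlation `rho`, thresholded at the normal
  quantile of each SNP's MAF — marginals stay Binomial(2, MAF) while
  neighbours correlate. Thresholding attenuates the product-moment
  correlation below `rho`; tests therefore compare against a Monte-Carlo
  oracle of the same construction rather than against `rho` itself.
* **Covariates** reproduce the cohort's marginal frequencies (78% male,
  94% smokers, ECOG 0/1/2 at 33/66/1%, four histologies, three treatment
  regimens, two arms).
* **Phenotype**: `P(y = 1) = plogis(b0 + sum(beta · code) + covariate
  terms)` with a small planted causal set. The intercept is calibrated by
  bisection against the *realized* labels: one uniform vector `u` is drawn,
  `y = 1{u < p(b0)}`, and since the positive count is monotone in `b0` the
  bisection lands the realized class-1 count on the target (178-sample
  cohorts really do get 41 non-responders). Pure binomial sampling would
  miss the target by several counts a third of the time.
* Defaults: 178 samples, 22 autosomes × 200 SNPs, class-1 fraction 41/178,
  no missingness (a configurable missing rate exercises the imputer).

What the generator does **not** emulate: coalescent-realistic haplotype
structure, population stratification, genotyping/imputation artefacts, and
linkage patterns beyond exchangeable within-block correlation. Tests
passing on these cohorts therefore demonstrate that the machinery is
correct and leakage-free under the assumed generative model, not that any
particular clinical cohort is classifiable.

## Numerical and design choices

* Standardization uses population (n-denominator) scaling; the variance
  filter must precede it, and an all-constant chromosome yields an
  empty-support partial model with a warning rather than an error.
* ANOVA selection keeps `ceiling(fraction × ncol)` features by smallest
  two-group F-test p-value, ties broken by column order; a feature
  identical to the labels gets p = 0.
* RFE removes `max(1, floor(step × current))` features per round, never
  dropping below the target; the wrapped L1 model uses `C = 1`.
* Subsample draws, CV folds, resampling and classifier randomness all
  derive from one master seed through an integer mixing function, so a run
  is reproducible byte-for-byte, including across the 36-experiment grid
  (each experiment gets an independent child seed).
* Random forests run single-threaded with a fixed seed (impurity
  importance); KNN ties are seeded.
* A failed experiment is recorded as failed and the grid continues.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(
  n_samples = 400, n_snps_per_chromosome = c(rep(30, 3), rep(0, 19)),
  causal_snps = tibble::tibble(chrom = c(1, 2, 3), index = c(5, 12, 20),
                               beta = log(3)),
  class_fraction = 0.3, seed = 1)
cohort <- simulate_cohort(cfg)
splits <- stratified_three_way_split(cohort, seed = 1)
config <- run_config(S = 20, W = 10, reduced_grids = TRUE, seed = 1,
                     fs_methods = "anova", samplings = c("none", "up"),
                     classifiers = "linear_svm")
grid <- run_experiment_grid(splits, config)
tidy(grid)
autoplot(grid)
```

The problem sizes used throughout the test-suite and the acceptance script
are the package's chosen desk-scale study conditions: unit fixtures of
30–400 samples with tens of SNPs, one genome-scale recovery cohort of
2000 samples × 22 × 200 SNPs with ten causal SNPs of per-allele odds ratio
2 (`S = 100`, merge at `W = S/2`, SVM cost grid {1, 10}), and a
240-sample null cohort for the leakage checks. On the recovery cohort the
planted SNPs' mean stability score far exceeds the 95th percentile of the
noise scores, and the final model's CV weighted F1 beats its 20-permutation
null; on null cohorts every sampling method — including up-sampling, the
classic leakage amplifier — stays inside the permutation band, because
resampling only ever touches training folds.

## Catalog intersection

Selected SNPs can be intersected with GWAS Catalog association records.
Loading deduplicates to unique (chromosome, position, trait) triples,
discards multi-SNP interaction entries, and keeps associations with
p < 10^-6. Trait filtering is exact string matching (after whitespace
normalization) against shipped vocabularies: a narrow lung-cancer list and
an extended cancer list that contains it. Genome builds must be declared on
both sides of a positional intersection; no liftover is attempted. Both
positional and rsid matching are provided, since either convention occurs
in practice.

## Known limitations

* The stability filter selects features using stability-set labels outside
  the final CV loop; the independent stability set reduces, but does not
  remove, model-selection bias. A nested outer CV would remove it at
  `S`-fold cost and is deliberately out of scope.
* Weighted F1 under heavy imbalance has a high all-majority baseline
  (about 0.67 at a 23% minority); margins over that baseline are the
  meaningful signal, which is why permutation nulls accompany every
  headline score.
* KNN has no intrinsic feature metric; its rankings inherit the feature
  selector's statistic.
* Only the additive inheritance encoding and a linear SVM kernel are
  supported, by design.
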