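---
title: "Sex-aware models of genetically regulated expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-aware models of genetically regulated expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the pipeline answers

Genetically regulated expression (GReX) models predict a gene's expression
as a weighted sum of cis-SNP dosages, with weights learned in a reference
panel that has both genotypes and RNA-seq. The weights are usually trained
on males and females together. For genes whose cis regulation differs by
sex, a single set of weights is a compromise: it dilutes the sex-specific
signal, and it can mask genes that are only predictable in one sex. `sagex`
quantifies this per gene. It trains three weight sets — whole-sample,
male-only, female-only — applies all three in an independent cohort, and
tests, within each sex, whether the sex-specific weights predict observed
expression better than the whole-sample weights.

## Training: penalized regression with nested cross-validation

For each gene, candidate predictors are biallelic SNP dosages within ±1 Mb
of the transcription start site (inclusive on both ends). The fit is an
elastic net at mixing parameter α = 0.5 — the convention for transcriptome
imputation, balancing the lasso's sparsity against ridge stability among
correlated cis-SNPs — via `glmnet`, with dosage columns standardized
internally for penalty fairness across allele frequencies and weights
reported back on the per-dosage scale. Neither the window size nor α is
sacred; both are config keys (`window_bp`, `alpha`).

Performance must be estimated out-of-sample while λ is itself tuned, so the
cross-validation is nested: a 10-fold outer loop, and within each outer
training set a 10-fold inner `cv.glmnet` that picks λ at minimum mean CV
error. The held-out prediction for outer fold *k* is the genetic component
only, `X β̂(λₖ)` without the fitted intercept. This matches how the
persisted weights are later applied (the weight-database format stores no
intercepts), and it matters statistically: a per-fold intercept equals the
fold-training mean, which is negatively correlated with the held-out fold
mean, so intercept-carrying out-of-fold predictions acquire a spurious
correlation with the outcome. During development this inflated the
pass rate of pure-noise genes through the model filters to roughly 30 %;
with genetic-component predictions the measured null pass rate is at the
nominal level (the test suite holds it ≤ 6 % over 200 noise genes).

The reported statistics are

* `cv_r2` — squared Pearson correlation between the pooled out-of-fold
  predictions and observed expression;
* `cv_pvalue` — the two-sided correlation-test p-value (df = n − 2) of that
  same correlation.

Deliverable weights are a full-data refit at the λ selected by inner CV on
the full data; the CV metrics stay honest out-of-sample quantities. Models
are retained when `cv_r2 > 0.01` **and** `cv_pvalue < 0.05` (both strict; a
model at exactly 0.01 is dropped). Genes where the elastic net selects zero
SNPs are "no model" genes — absent from the model set rather than stored
with empty weights. Sex-stratified runs subset samples first, recompute
per-stratum allele frequencies, and drop within-stratum monomorphic
variants: a SNP with no variation in females cannot carry female weight.

Fold assignment is deterministic given the seed and *tied to sample ids*
(folds are dealt over the sorted ids under a seeded permutation), so
results are invariant to row order; per-gene sub-seeds are derived by
hashing the global seed with the stratum and gene id, so per-gene results
do not depend on which other genes are run.

Two numerical conventions inherited from `glmnet` are worth stating. First,
it internally scales the response to unit (1/n)-variance and λ with it, so
the effective ridge penalty is λ/sd(y); the test-suite oracle (an
independent coordinate-descent solver) reproduces this convention, and the
closed-form ridge check is run on a unit-variance response where the
documented objective is exact. Second, `glmnet` requires at least two
predictor columns; single-SNP genes are fitted with an inert all-zero pad
column, which cannot change the optimum for the real column.

## Expression processing

The expression pipeline is the standard eQTL preparation, enforced in order
by a state tag on the matrix (raw → filtered → quantile-normalized →
inverse-normal → residualized; out-of-order calls error):

1. **Expression filter** — keep genes with > 0.1 RPKM and > 5 reads
   (strict) in ≥ 10 samples (inclusive).
2. **Quantile normalization to the average empirical distribution** — the
   reference is the mean of the per-sample order statistics; ties receive
   the mean of the tied reference positions. This tie rule is why the step
   is implemented directly rather than delegated (library implementations
   interpolate at the average rank, which differs for ties of length > 2);
   on tie-free data the tests confirm exact agreement with
   `limma::normalizeQuantiles`.
3. **Inverse normal transform per gene** — `qnorm(rank/(n+1))` with average
   ranks for ties; the `rank/(n+1)` offset (no Blom correction) is the
   reference-pipeline convention.
4. **Residualization** — OLS residuals on an intercept plus the covariate
   matrix (supplied precomputed: latent expression factors, genetic PCs,
   platform, sex). Constant columns are dropped with a warning, which lets
   one code path serve stratified runs where sex is constant. PEER-factor
   estimation is deliberately out of scope. A config flag
   (`residualize_within_stratum`, default off) re-estimates covariate
   effects within each sex for users who prefer that reading; the default
   residualizes once on the full sample, before both whole-sample and
   stratified model building, and the transform order (inverse-normal, then
   residualize) follows the reference pipeline.

## Genotype QC

Variant filters implement the printed post-imputation inequalities
literally, because they come in both exclusion and retention form:
exclusion is strict (MAF < 0.01, missingness > 0.05, Hardy–Weinberg
p < 1e-6) and retention is strict (imputation R² > 0.8, so R² exactly 0.8
is dropped). Hardy–Weinberg is a 1-df chi-square on hard calls obtained by
rounding dosages — the equilibrium test is undefined on continuous dosages.
MAF is computed over non-missing dosages only; missingness is its own
filter. The removal log records the first failing rule per variant in a
fixed order (MAF, imputation R², missingness, HWE, biallelic-SNP), and
filtering is idempotent. Coordinates are 1-based (VCF convention)
throughout; BED annotation is converted on read, strand-aware.

## Prediction in an independent cohort

Model SNPs are matched to cohort variants by id and harmonized by allele
pair: same orientation uses the dosage as-is, swapped orientation uses
2 − dosage, strand-ambiguous pairs (A/T, C/G) are dropped conservatively
(synthetic panels avoid them by construction; on real data
frequency-matching would be the alternative), and anything else is a
mismatch drop. Model SNPs absent from the cohort contribute zero and lower
the gene's coverage — the downstream uninformativeness filter (drop genes
with > 90 % zero predictions, strict; zero means |value| < 1e-12, the
tolerance for floating-point sums of exact zeros) then catches genes with
no usable SNPs. Missing dosages are mean-imputed within variant.

## Validation and the bootstrap

Within each sex: observed expression is regressed (OLS) on the
sex-specific prediction and, separately, on the whole-sample prediction.
R² is the squared Pearson correlation; the p-value is the correlation test
(identical to the slope t-test). A gene *validates sex-specifically* when
β > 0, p < 0.05 and R²(sex) > R²(whole), all strict; the mirrored
conditions define whole-sample validation; positive but non-significant
association is reported as direction-consistent. The four categories
partition all testable genes; genes whose prediction has zero variance in
the cohort are not testable and are reported as such rather than assigned
R² = 0. No multiple-testing correction is applied — the criteria are
per-gene at p < 0.05 by design — and the bootstrap then guards the claim
that a validated improvement is real.

ΔR² = R²(sex) − R²(whole) is bootstrapped by resampling *individuals* with
replacement, jointly across the observed vector and both predictions so
the pairing is preserved (resampling cases, not residuals, is the
assumption-light choice). The interval is the percentile interval over
1000 resamples at 95 %; degenerate resamples (a constant predictor) are
redrawn up to 10 times, then excluded with a count. "Significantly better
prediction" means this interval excludes zero. Coverage is verified by
simulation in the test suite at a true ΔR² of 0 and of 0.08 (constructed
from nested linear models with known population R²), with observed
coverage required in 90–98 % over 200 replications.

## The synthetic study

The generator draws one variant panel (per-gene cis windows on one
chromosome, MAF uniform on a configurable range, non-strand-ambiguous
allele pairs) and then independent Binomial(2, MAF) dosages per cohort:
training and validation cohorts share the architecture but not the
samples. Genes belong to four classes — shared, male-specific,
female-specific, null — apportioned by largest remainder, so an even mix
over 100 genes gives exactly 25 per class. Expression is

y = Σₖ β₍ₖ,ₛ₎ dₖ + Σⱼ γⱼ cⱼ + ε,  ε ~ N(0, σ²ₛ),

with sex-interaction effects (not mean shifts, which residualization would
remove anyway), Gaussian covariates jointly explaining 20 % of variance by
default, and β scaled against the theoretical dosage variance
2·maf·(1−maf) so the same effect vector yields the target per-sex
heritability in expectation in every cohort; σ²ₛ absorbs the remainder so
total variance is 1. Defaults mirror a sex-stratified eQTL study: 566
training samples (34.5 % female), 349 validation samples, h² = 0.3 for
classes with an effect — a deliberately clear signal at stratified sample
sizes, as true sex-specific effect sizes are not well characterized.

What the generator does *not* emulate: linkage disequilibrium (variants
are independent, which is what makes weight recovery directly checkable),
population structure, RNA-seq count noise, trans effects, and X-chromosome
dosage compensation. Passing tests therefore demonstrate that the
estimator and decision rules work when their assumptions hold — additive,
LD-free cis signals — not that real-data performance will match; with LD,
weights are identified only up to the correlation structure, and the
per-gene validation fractions would be less sharp.

Realized per-sex heritability (variance of the true genetic values over
variance of expression, within sex) is recorded in the ground truth. Its
per-gene Monte-Carlo standard deviation is about 0.017 at 1000 samples per
sex, so accuracy is asserted on the replicate mean (within ±0.03 of
target over 20 genes) with a loose per-gene sanity band, not per gene.

## Problem sizes in the test and acceptance runs

The test suite exercises the estimator at study scale chosen for a
single-CPU run: the oracle comparison on 20 random instances (n ≤ 50,
p ≤ 10); null calibration on 200 noise genes at n = 300; heritability
monotonicity with 20 genes per level at n = 1000; the end-to-end study
with 100 genes at 400 training / 200 validation samples per sex and 1000
bootstrap replicates; bootstrap coverage with 200 replications at n = 250.
The acceptance script reruns the end-to-end study at the same size. These
sizes are the package's documented operating points; all scale linearly in
genes and near-linearly in samples.

## Known limitations

* Autosomal, additive, cis-only by scope; no multi-tissue borrowing,
  annotation priors, or shrinkage-based weight training.
* The validation regression is within sex also for whole-sample weights;
  cross-sex validation is not implemented.
* Strand-ambiguous SNPs are always dropped at prediction time; there is no
  frequency-based rescue.
* The bootstrap is percentile-on-cases only; studentized or BCa intervals
  are not offered.
* The null calibration of the model filters is nominal under exchangeable
  noise; heavy-tailed expression noise is not modeled by the generator.
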