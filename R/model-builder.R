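#' Select candidate cis-SNPs around a gene's transcription start site
#'
#' @param gene_tss 1-based TSS position.
#' @param variants variant data.frame (`id`, `chrom`, `pos`).
#' @param window_bp half-window in base pairs; variants with position in
#'   `[tss - window, tss + window]` (inclusive both ends) are returned.
#' @param chrom chromosome of the TSS; must be present in the variant table's
#'   chromosome set.
#' @return Character vector of variant ids.
#' @export
select_cis_snps <- function(gene_tss, variants, window_bp = 1e6,
                            chrom = NULL) {
  if (is.null(chrom)) {
    chrom <- unique(variants$chrom)
    if (length(chrom) > 1)
      stop("variants span multiple chromosomes; supply `chrom`")
  }
  if (!chrom %in% variants$chrom)
    stop("unknown chromosome: ", chrom)
  hit <- variants$chrom == chrom &
    variants$pos >= gene_tss - window_bp & variants$pos <= gene_tss + window_bp
  variants$id[hit]
}

# Deterministic fold assignment tied to sample ids: folds are assigned to
# the *sorted* ids under a seeded permutation, so a sample keeps its fold no
# matter how the input rows are ordered.
make_foldid <- function(sample_ids, k, seed) {
  ord <- sort(sample_ids)
  set.seed(seed)
  shuffled <- sample(ord)
  fold <- rep(seq_len(k), length.out = length(ord))
  names(fold) <- shuffled
  unname(fold[sample_ids])
}

#' Elastic-net coefficients at a fixed penalty
#'
#' Fits the elastic net `(1/2n)||y - b0 - Xb||^2 +
#' lambda * (alpha * ||b||_1 + (1-alpha)/2 * ||b||_2^2)` via glmnet and
#' returns the coefficients at the requested lambda. glmnet's convention
#' applies: the response is internally scaled to unit (1/n)-variance and
#' lambda with it, so the effective ridge penalty is `lambda / sd_n(y)`
#' (for a response already on unit scale the documented objective holds
#' exactly). This is the single-fit primitive underlying [fit_gene_model()];
#' exposing it keeps the penalized fit independently checkable against a
#' direct coordinate-descent solver.
#'
#' @param x predictor matrix (n x p, p >= 1).
#' @param y response vector.
#' @param lambda penalty value (single number).
#' @param alpha elastic-net mixing parameter (1 = lasso, 0 = ridge).
#' @param standardize standardize columns internally (coefficients are
#'   always returned on the original scale).
#' @param intercept include an unpenalized intercept.
#' @return Named numeric vector: `(Intercept)` followed by one coefficient
#'   per column of `x`.
#' @export
enet_coefficients <- function(x, y, lambda, alpha = 0.5,
                              standardize = FALSE, intercept = TRUE) {
  x <- as.matrix(x)
  single <- ncol(x) == 1
  # glmnet needs >= 2 columns; an all-zero pad column cannot attract weight
  # and leaves the optimum for the real columns unchanged
  xfit <- if (single) cbind(x, 0) else x
  # fit along a short descending path ending at the target (warm starts give
  # the exact path solution at `lambda`)
  path <- lambda * c(16, 8, 4, 2, 1)
  fit <- glmnet::glmnet(xfit, y, alpha = alpha, standardize = standardize,
                        intercept = intercept, thresh = 1e-14,
                        lambda = path)
  cf <- as.numeric(coef(fit)[, length(path)])
  if (single) cf <- cf[1:2]
  names(cf) <- c("(Intercept)", colnames(x) %||%
                   paste0("x", seq_len(ncol(x))))
  cf
}

#' Fit one gene's cis elastic-net model with nested cross-validation
#'
#' Outer K-fold loop: for each outer fold the penalty is chosen by inner
#' cross-validation (`cv.glmnet`, lambda at minimum mean CV error) on the
#' outer-training portion only, and predictions for the held-out fold are
#' the genetic component — the weighted dosage sum at the selected penalty,
#' without the fitted intercept, mirroring how persisted weights are applied
#' to an independent cohort (a per-fold intercept would also leak the fold
#' mean and inflate the null). The cross-validated performance is the
#' squared Pearson correlation
#' between the pooled out-of-fold predictions and the observed expression,
#' with its two-sided correlation-test p-value. The deliverable weights are
#' a full-data refit at the lambda selected by inner cross-validation on the
#' full data; the CV metrics remain honest out-of-sample quantities.
#'
#' Dosage columns are standardized internally (penalty fairness across
#' allele frequencies); reported weights are on the per-dosage scale.
#'
#' @param dosages n x p dosage matrix (rownames sample ids, colnames variant
#'   ids); missing values are not allowed here — impute upstream.
#' @param expression numeric response vector of length n.
#' @param gene_id gene identifier recorded in the model.
#' @param stratum label recorded in the model (`all`, `male`, `female`).
#' @param alpha elastic-net mixing parameter.
#' @param n_outer_folds,n_inner_folds fold counts for the outer performance
#'   loop and inner lambda selection.
#' @param seed integer; fold assignment (tied to sample ids) and any RNG in
#'   the fit derive from it.
#' @return A `gene_model`: `gene_id`, `stratum`, `weights` (data.frame
#'   `variant_id`, `weight`; may have zero rows when the elastic net selects
#'   no SNPs), `n_snps_in_window`, `n_snps_in_model`, `cv_r2`, `cv_pvalue`,
#'   `alpha`, `lambda`, `seed`.
#' @export
fit_gene_model <- function(dosages, expression, gene_id = "gene",
                           stratum = "all", alpha = 0.5,
                           n_outer_folds = 10, n_inner_folds = 10,
                           seed = 1L) {
  x <- as.matrix(dosages)
  y <- as.numeric(expression)
  n <- nrow(x)
  if (length(y) != n) stop("dosages and expression must share samples")
  if (n < 2 * n_outer_folds)
    stop(sprintf("need >= %d samples for %d outer folds",
                 2 * n_outer_folds, n_outer_folds))
  if (sd(y) == 0) stop("expression has zero variance")
  ids <- rownames(x) %||% as.character(seq_len(n))
  single <- ncol(x) == 1
  if (single) x <- cbind(x, 0)  # glmnet needs >= 2 columns; zero pad is inert

  outer_fold <- make_foldid(ids, n_outer_folds, derive_seed(seed, "outer"))
  oof <- rep(NA_real_, n)
  for (k in seq_len(n_outer_folds)) {
    tr <- outer_fold != k
    inner <- make_foldid(ids[tr], n_inner_folds,
                         derive_seed(seed, "inner", k))
    cvfit <- glmnet::cv.glmnet(x[tr, , drop = FALSE], y[tr], alpha = alpha,
                               foldid = inner, standardize = TRUE)
    # held-out predictions are the genetic component only (no intercept):
    # this is exactly how the stored weights are applied to a new cohort,
    # and it avoids the fold-mean artifact that makes constant per-fold
    # intercept predictions spuriously correlate with the outcome
    cf_k <- drop(coef(cvfit, s = "lambda.min"))[-1]
    oof[!tr] <- drop(x[!tr, , drop = FALSE] %*% cf_k)
  }
  if (sd(oof) > 0) {
    ct <- cor.test(oof, y)
    cv_r2 <- unname(ct$estimate)^2
    cv_pvalue <- ct$p.value
  } else {
    cv_r2 <- 0
    cv_pvalue <- 1
  }

  inner_full <- make_foldid(ids, n_inner_folds, derive_seed(seed, "final"))
  cvfit <- glmnet::cv.glmnet(x, y, alpha = alpha, foldid = inner_full,
                             standardize = TRUE)
  lambda <- cvfit$lambda.min
  cf <- drop(coef(cvfit, s = "lambda.min"))[-1]
  if (single) cf <- cf[1]
  names(cf) <- colnames(dosages) %||% paste0("snp_", seq_along(cf))
  nz <- cf[cf != 0]
  structure(list(
    gene_id = gene_id, stratum = stratum,
    weights = data.frame(variant_id = names(nz), weight = unname(nz),
                         stringsAsFactors = FALSE),
    n_snps_in_window = ncol(dosages), n_snps_in_model = length(nz),
    cv_r2 = cv_r2, cv_pvalue = cv_pvalue,
    alpha = alpha, lambda = lambda, seed = seed), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s [%s]: %d/%d SNPs, cv R2 = %.3f (p = %.3g)\n",
              x$gene_id, x$stratum, x$n_snps_in_model, x$n_snps_in_window,
              x$cv_r2, x$cv_pvalue))
  invisible(x)
}

#' Bundle gene models into a model set
#'
#' @param models list of `gene_model` objects (one stratum). Models whose
#'   elastic net selected no SNPs are dropped: a gene with an empty weight
#'   set has no prediction model.
#' @param stratum stratum label; defaults to the models' shared label.
#' @param n_samples training sample count recorded as metadata.
#' @return A `model_set`: models keyed by gene id plus metadata.
#' @export
model_set <- function(models, stratum = NULL, n_samples = NA_integer_) {
  models <- Filter(function(m) m$n_snps_in_model > 0, models)
  if (is.null(stratum))
    stratum <- if (length(models)) models[[1]]$stratum else "all"
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  if (anyDuplicated(names(models)))
    stop("duplicate gene ids in model set")
  structure(list(stratum = stratum, models = models,
                 n_samples = as.integer(n_samples)),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  r2 <- vapply(x$models, `[[`, numeric(1), "cv_r2")
  cat(sprintf("model_set [%s]: %d genes, n = %s, mean cv R2 = %.3f\n",
              x$stratum, length(x$models),
              ifelse(is.na(x$n_samples), "?", x$n_samples),
              if (length(r2)) mean(r2) else NA))
  invisible(x)
}

#' Filter gene models on cross-validated performance
#'
#' Retains models with cross-validated R-squared strictly above `r2_min`
#' *and* p-value strictly below `p_max` (defaults 0.01 and 0.05, the
#' standard transcriptome-model thresholds; a model at exactly R2 = 0.01 is
#' dropped).
#'
#' @param models a `model_set` or list of `gene_model`s.
#' @param r2_min,p_max strict thresholds.
#' @return A filtered `model_set`.
#' @export
filter_models <- function(models, r2_min = 0.01, p_max = 0.05) {
  ms <- if (inherits(models, "model_set")) models else model_set(models)
  keep <- Filter(function(m) m$cv_r2 > r2_min && m$cv_pvalue < p_max,
                 ms$models)
  structure(list(stratum = ms$stratum, models = keep,
                 n_samples = ms$n_samples), class = "model_set")
}

#' Build whole-sample and sex-stratified model sets
#'
#' Runs three independent model builds — full sample, males only, females
#' only. Within each stratum, variant MAF is recomputed on the stratum's
#' samples and variants monomorphic there are dropped (a SNP with no
#' variation in one sex cannot carry weight in that sex); per-gene cis-SNPs
#' are selected around the TSS, models are fitted by [fit_gene_model()] with
#' a per-gene sub-seed, and the performance filters of [filter_models()] are
#' applied. Missing dosages are mean-imputed within variant for fitting.
#'
#' @param genotypes a [genotype_matrix()] (training cohort, post-QC).
#' @param expression an [expression_matrix()], usually `residualized`.
#' @param sex_labels named character vector (`male`/`female`) covering all
#'   expression samples.
#' @param annotation gene annotation data.frame (`gene_id`, `chrom`, `tss`),
#'   e.g. from [read_gene_annotation()]. Genes absent from the expression
#'   matrix are skipped.
#' @param config list of build parameters: `window_bp` (1e6), `alpha` (0.5),
#'   `n_outer_folds` (10), `n_inner_folds` (10), `r2_min` (0.01), `p_max`
#'   (0.05), `seed` (1), `strata` (`c("all", "male", "female")`).
#' @return Named list of filtered `model_set`s, one per stratum.
#' @export
build_stratified_models <- function(genotypes, expression, sex_labels,
                                    annotation, config = list()) {
  cfg <- utils::modifyList(
    list(window_bp = 1e6, alpha = 0.5, n_outer_folds = 10,
         n_inner_folds = 10, r2_min = 0.01, p_max = 0.05, seed = 1L,
         strata = c("all", "male", "female")), config)
  samples <- expression$sample_ids
  if (!all(samples %in% names(sex_labels)))
    stop("every expression sample needs a sex label")
  if (!all(samples %in% genotypes$sample_ids))
    stop("every expression sample needs genotypes")
  sex <- sex_labels[samples]

  out <- list()
  for (stratum in cfg$strata) {
    ids <- if (stratum == "all") samples else samples[sex == stratum]
    if (length(ids) < 2 * cfg$n_outer_folds)
      stop(sprintf("stratum '%s' has %d samples; need >= %d for %d outer folds",
                   stratum, length(ids), 2 * cfg$n_outer_folds,
                   cfg$n_outer_folds))
    gm <- subset_genotypes(genotypes, samples = ids)
    poly <- gm$variants$id[!is.na(gm$variants$maf) & gm$variants$maf > 0]
    gm <- subset_genotypes(gm, variants = poly)
    d <- gm$dosages
    if (anyNA(d))
      for (j in which(colSums(is.na(d)) > 0))
        d[is.na(d[, j]), j] <- mean(d[, j], na.rm = TRUE)

    models <- list()
    for (g in seq_len(nrow(annotation))) {
      gene <- annotation$gene_id[g]
      if (!gene %in% expression$gene_ids) next
      cis <- tryCatch(
        select_cis_snps(annotation$tss[g], gm$variants,
                        window_bp = cfg$window_bp,
                        chrom = annotation$chrom[g]),
        error = function(e) character(0))
      if (!length(cis)) next
      models[[gene]] <- fit_gene_model(
        d[, cis, drop = FALSE], expression$values[ids, gene],
        gene_id = gene, stratum = stratum, alpha = cfg$alpha,
        n_outer_folds = cfg$n_outer_folds,
        n_inner_folds = cfg$n_inner_folds,
        seed = derive_seed(cfg$seed, stratum, gene))
    }
    ms <- model_set(unname(models), stratum = stratum,
                    n_samples = length(ids))
    out[[stratum]] <- filter_models(ms, cfg$r2_min, cfg$p_max)
    # alleles for downstream harmonization
    for (gene in names(out[[stratum]]$models)) {
      w <- out[[stratum]]$models[[gene]]$weights
      idx <- match(w$variant_id, gm$variants$id)
      w$effect_allele <- gm$variants$alt[idx]
      w$other_allele <- gm$variants$ref[idx]
      out[[stratum]]$models[[gene]]$weights <- w
    }
  }
  out
}
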