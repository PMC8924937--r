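#' Configuration for the synthetic two-cohort study
#'
#' Defines the generative model behind the synthetic genotype/expression
#' cohorts: per-gene cis windows of independent biallelic SNPs, additive
#' genetic effects that are shared between the sexes, male-specific,
#' female-specific, or absent, Gaussian covariate structure, and Gaussian
#' noise scaled so each gene hits its target per-sex cis heritability in
#' expectation. Training and validation cohorts are independent draws from
#' one model: the variant panel, causal variants and effect sizes are shared,
#' the samples are not.
#'
#' Default cohort sizes mirror a sex-stratified transcriptome-model study:
#' a training cohort of 566 (195 female / 371 male) and a validation cohort
#' of 349 (178 female / 171 male).
#'
#' @param n_train,n_validate cohort sizes.
#' @param frac_female expected fraction of female samples (applied to each
#'   cohort; counts are rounded).
#' @param n_genes number of genes.
#' @param cis_snps_per_gene candidate cis-SNPs per gene.
#' @param n_causal causal SNPs per non-null gene (must be <=
#'   `cis_snps_per_gene`).
#' @param maf_range length-2 numeric; MAFs are drawn uniformly in this range
#'   (within (0.01, 0.5\]).
#' @param gene_class_mix named proportions over
#'   `c(shared, male_specific, female_specific, null)`; must sum to 1.
#'   Class counts are assigned by largest-remainder rounding, so e.g. an
#'   even mix over 100 genes gives exactly 25 genes per class.
#' @param h2_male,h2_female target cis heritability per sex for genes of a
#'   class carrying effects in that sex (classes with no effect in a sex
#'   have heritability 0 there by construction).
#' @param n_covariates number of Gaussian covariates; together they explain
#'   `covar_var` of expression variance.
#' @param covar_var total expression variance attributed to covariates.
#' @param seed integer seed; all randomness derives from it.
#' @return A `simulation_config` object (validated list).
#' @export
simulation_config <- function(n_train = 566, n_validate = 349,
                              frac_female = 0.345, n_genes = 100,
                              cis_snps_per_gene = 20, n_causal = 3,
                              maf_range = c(0.05, 0.5),
                              gene_class_mix = c(shared = 0.25,
                                                 male_specific = 0.25,
                                                 female_specific = 0.25,
                                                 null = 0.25),
                              h2_male = 0.3, h2_female = 0.3,
                              n_covariates = 5, covar_var = 0.2,
                              seed = 1L) {
  if (n_train <= 0 || n_validate <= 0 || n_genes <= 0 ||
      cis_snps_per_gene <= 0)
    stop("sample, gene and variant counts must be positive")
  if (frac_female <= 0 || frac_female >= 1)
    stop("frac_female must lie in (0, 1)")
  if (n_causal > cis_snps_per_gene)
    stop("n_causal must not exceed cis_snps_per_gene")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must be increasing within (0, 0.5]")
  classes <- c("shared", "male_specific", "female_specific", "null")
  if (!setequal(names(gene_class_mix), classes))
    stop("gene_class_mix must be named over: ", paste(classes, collapse = ", "))
  gene_class_mix <- gene_class_mix[classes]
  if (abs(sum(gene_class_mix) - 1) > 1e-8)
    stop("gene_class_mix must sum to 1")
  if (h2_male < 0 || h2_male >= 1 || h2_female < 0 || h2_female >= 1)
    stop("heritabilities must lie in [0, 1)")
  if (h2_male + covar_var >= 1 || h2_female + covar_var >= 1)
    stop("h2 + covar_var must be < 1 (residual noise variance must be positive)")
  structure(list(n_train = as.integer(n_train),
                 n_validate = as.integer(n_validate),
                 frac_female = frac_female, n_genes = as.integer(n_genes),
                 cis_snps_per_gene = as.integer(cis_snps_per_gene),
                 n_causal = as.integer(n_causal), maf_range = maf_range,
                 gene_class_mix = gene_class_mix, h2_male = h2_male,
                 h2_female = h2_female,
                 n_covariates = as.integer(n_covariates),
                 covar_var = covar_var, seed = as.integer(seed)),
            class = "simulation_config")
}

# Largest-remainder apportionment of n genes to the class mix.
class_counts <- function(mix, n) {
  raw <- mix * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

CIS_WINDOW_BP <- 1e6
GENE_SPACING_BP <- 2.5e6   # > 2 * window: cis windows never overlap

#' Simulate genotypes for the training and validation cohorts
#'
#' One variant panel is drawn (positions inside per-gene cis windows on a
#' single chromosome, MAFs uniform in `maf_range`, non-strand-ambiguous
#' allele pairs) and then dosages are sampled independently per cohort and
#' per sample as Binomial(2, MAF) — independent variants, no linkage
#' disequilibrium, which makes downstream weight recovery directly
#' checkable. Imputation quality metadata is set to 1.
#'
#' @param config a [simulation_config()].
#' @return A list with `train` and `validate` ([genotype_matrix()] objects
#'   sharing one variant panel), `genes` (data.frame: `gene_id`, `chrom`,
#'   `tss`, `strand`), and `sex` (list of named character vectors
#'   `male`/`female` per cohort).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "genotypes"))
  G <- config$n_genes
  V <- config$cis_snps_per_gene
  tss <- CIS_WINDOW_BP + GENE_SPACING_BP * (seq_len(G) - 1) + 1
  genes <- data.frame(gene_id = sprintf("GENE%04d", seq_len(G)),
                      chrom = "1", tss = as.integer(tss), strand = "+",
                      stringsAsFactors = FALSE)
  # one panel: positions unique within the genome because windows are disjoint
  pos <- unlist(lapply(tss, function(t)
    sort(sample(seq(t - CIS_WINDOW_BP + 1, t + CIS_WINDOW_BP - 1), V))))
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                  byrow = TRUE)  # non-strand-ambiguous pairs only
  pick <- sample(nrow(pairs), G * V, replace = TRUE)
  maf <- runif(G * V, config$maf_range[1], config$maf_range[2])
  variants <- data.frame(
    id = paste0("1_", pos), chrom = "1", pos = as.integer(pos),
    ref = pairs[pick, 1], alt = pairs[pick, 2],
    imputation_r2 = 1.0, biallelic_snp = TRUE,
    gene_id = rep(genes$gene_id, each = V),
    maf_target = maf,
    stringsAsFactors = FALSE)

  draw_cohort <- function(n, prefix, tag) {
    set.seed(derive_seed(config$seed, "dosages", tag))
    d <- vapply(maf, function(f) rbinom(n, 2, f), numeric(n))
    rownames(d) <- sprintf("%s%04d", prefix, seq_len(n))
    genotype_matrix(d, variants)
  }
  train <- draw_cohort(config$n_train, "train_", "train")
  validate <- draw_cohort(config$n_validate, "val_", "validate")

  draw_sex <- function(ids, tag) {
    set.seed(derive_seed(config$seed, "sex", tag))
    n_f <- round(config$frac_female * length(ids))
    sex <- rep("male", length(ids))
    sex[sample(length(ids), n_f)] <- "female"
    names(sex) <- ids
    sex
  }
  list(train = train, validate = validate, genes = genes,
       sex = list(train = draw_sex(train$sample_ids, "train"),
                  validate = draw_sex(validate$sample_ids, "validate")))
}

# Draw per-gene ground truth (class, causal SNPs, per-sex effects) for a
# fixed variant panel. Effects are scaled against the *theoretical* dosage
# variance 2*maf*(1-maf) so that the same effect vector yields the target
# heritability in expectation in every cohort drawn from the panel.
draw_ground_truth <- function(variants, genes, config) {
  set.seed(derive_seed(config$seed, "effects"))
  counts <- class_counts(config$gene_class_mix, config$n_genes)
  class <- rep(names(counts), counts)
  truth <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    vg <- variants[variants$gene_id == genes$gene_id[g], , drop = FALSE]
    causal <- sort(sample(nrow(vg), config$n_causal))
    b_raw <- rnorm(config$n_causal)
    vvar <- 2 * vg$maf_target[causal] * (1 - vg$maf_target[causal])
    scale_to <- function(h2) {
      if (h2 == 0) return(rep(0, config$n_causal))
      b_raw * sqrt(h2 / sum(b_raw^2 * vvar))
    }
    h2m <- switch(class[g], shared = , male_specific = config$h2_male, 0)
    h2f <- switch(class[g], shared = , female_specific = config$h2_female, 0)
    truth[[g]] <- list(gene_id = genes$gene_id[g], class = class[g],
                       causal_ids = vg$id[causal],
                       beta_male = scale_to(h2m), beta_female = scale_to(h2f),
                       h2_male = h2m, h2_female = h2f)
  }
  truth
}

#' Simulate expression given genotypes and sex labels
#'
#' For each gene and sex, expression is the additive genetic value (sum of
#' per-sex causal effects times dosage) plus a shared covariate term and
#' Gaussian noise whose variance is set so that the genetic fraction of
#' total variance equals the class's target heritability for that sex in
#' expectation (total variance 1). Sex-specific effects are interaction
#' effects, not mean shifts — mean sex differences are removed downstream by
#' residualization anyway, so they would carry no signal.
#'
#' @param genotypes a [genotype_matrix()] from [simulate_genotypes()] (its
#'   variant table must carry the simulated `gene_id` and `maf_target`
#'   columns via [simulate_cohorts()]; see that function for the usual entry
#'   point).
#' @param sex_labels named character vector (`male`/`female`) over the
#'   genotype samples.
#' @param config the [simulation_config()].
#' @param ground_truth optional ground truth from a previous call (use the
#'   training cohort's truth when simulating the validation cohort so both
#'   share effects); NULL draws it.
#' @param tag cohort label used to decouple the noise stream between cohorts.
#' @return A list: `expression` (a raw [expression_matrix()]), `covariates`
#'   (samples x covariates matrix), and `ground_truth` (data.frame, one row
#'   per gene: class, causal ids, per-sex effects, target and realized
#'   per-sex heritability on this cohort).
#' @export
simulate_expression <- function(genotypes, sex_labels, config,
                                ground_truth = NULL, tag = "train") {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "simulation_config"))
  ids <- genotypes$sample_ids
  if (!setequal(names(sex_labels), ids))
    stop("genotypes and sex_labels must share sample ids")
  sex_labels <- sex_labels[ids]
  if (!all(sex_labels %in% c("male", "female")))
    stop("sex labels must be 'male' or 'female'")
  v <- genotypes$variants
  if (is.null(v$gene_id) || is.null(v$maf_target))
    stop("genotypes lack simulation annotation (gene_id / maf_target)")
  genes <- unique(v$gene_id)
  truth <- ground_truth %||%
    draw_ground_truth(v, data.frame(gene_id = genes), config)

  n <- length(ids)
  set.seed(derive_seed(config$seed, "covariates", tag))
  covariates <- matrix(rnorm(n * config$n_covariates), n,
                       dimnames = list(ids, paste0("COV", seq_len(config$n_covariates))))
  gamma <- rep(sqrt(config$covar_var / config$n_covariates),
               config$n_covariates)
  covar_term <- drop(covariates %*% gamma)

  is_male <- sex_labels == "male"
  expr <- matrix(NA_real_, n, length(genes), dimnames = list(ids, genes))
  realized <- matrix(NA_real_, length(genes), 2,
                     dimnames = list(genes, c("male", "female")))
  set.seed(derive_seed(config$seed, "noise", tag))
  for (g in seq_along(genes)) {
    tg <- truth[[g]]
    d <- genotypes$dosages[, tg$causal_ids, drop = FALSE]
    gval <- ifelse(is_male, drop(d %*% tg$beta_male),
                   drop(d %*% tg$beta_female))
    noise_sd <- ifelse(is_male,
                       sqrt(1 - tg$h2_male - config$covar_var),
                       sqrt(1 - tg$h2_female - config$covar_var))
    y <- gval + covar_term + rnorm(n) * noise_sd
    expr[, g] <- y
    for (s in c("male", "female")) {
      in_s <- (sex_labels == s)
      realized[g, s] <- if (sum(in_s) > 2 && var(y[in_s]) > 0)
        var(gval[in_s]) / var(y[in_s]) else NA_real_
    }
  }
  gt_df <- data.frame(
    gene_id = vapply(truth, `[[`, character(1), "gene_id"),
    class = vapply(truth, `[[`, character(1), "class"),
    causal_ids = vapply(truth, function(t) paste(t$causal_ids, collapse = ","),
                        character(1)),
    beta_male = vapply(truth, function(t) paste(signif(t$beta_male, 8),
                                                collapse = ","), character(1)),
    beta_female = vapply(truth, function(t) paste(signif(t$beta_female, 8),
                                                  collapse = ","), character(1)),
    h2_male = vapply(truth, `[[`, numeric(1), "h2_male"),
    h2_female = vapply(truth, `[[`, numeric(1), "h2_female"),
    realized_h2_male = realized[, "male"],
    realized_h2_female = realized[, "female"],
    stringsAsFactors = FALSE)
  list(expression = expression_matrix(expr, state = "raw"),
       covariates = covariates, ground_truth = gt_df, truth = truth)
}

#' Simulate a complete paired-cohort study
#'
#' Convenience wrapper: draws the variant panel, the per-gene ground truth,
#' and genotypes, sex, covariates and expression for both cohorts, with the
#' ground truth (classes, causal variants, effect sizes) shared between
#' cohorts.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `train` and `validate` (each: `genotypes`,
#'   `expression`, `covariates`, `sex`, `ground_truth`), plus `genes` (the
#'   annotation data.frame) and `config`.
#' @export
simulate_cohorts <- function(config) {
  geno <- simulate_genotypes(config)
  tr <- simulate_expression(geno$train, geno$sex$train, config, tag = "train")
  va <- simulate_expression(geno$validate, geno$sex$validate, config,
                            ground_truth = tr$truth, tag = "validate")
  list(train = list(genotypes = geno$train, expression = tr$expression,
                    covariates = tr$covariates, sex = geno$sex$train,
                    ground_truth = tr$ground_truth),
       validate = list(genotypes = geno$validate, expression = va$expression,
                       covariates = va$covariates, sex = geno$sex$validate,
                       ground_truth = va$ground_truth),
       genes = geno$genes, config = config)
}

#' Write a synthetic study to disk as pipeline-ready fixtures
#'
#' Emits, for each cohort, a VCF (GT:DS, INFO R2), an expression TSV, a
#' sample-metadata TSV (`sample_id`, `sex`), and a covariates TSV; plus a
#' gene-annotation BED (0-based half-open, strand-aware TSS) and the
#' ground-truth TSV. All files round-trip losslessly through
#' [load_genotypes()] / [read_expression_tsv()] up to dosage printing
#' precision.
#'
#' @param config a [simulation_config()], or a prebuilt [simulate_cohorts()]
#'   result.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named character vector: the file manifest.
#' @export
write_fixture_set <- function(config, out_dir) {
  study <- if (inherits(config, "simulation_config"))
    simulate_cohorts(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  manifest <- c()
  for (cohort in c("train", "validate")) {
    co <- study[[cohort]]
    write_vcf(co$genotypes, p(sprintf("%s.vcf", cohort)))
    write_expression_tsv(co$expression, p(sprintf("%s_expression.tsv", cohort)))
    write.table(data.frame(sample_id = names(co$sex), sex = unname(co$sex)),
                p(sprintf("%s_samples.tsv", cohort)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample_id = rownames(co$covariates),
                           co$covariates, check.names = FALSE),
                p(sprintf("%s_covariates.tsv", cohort)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- c(manifest,
                  setNames(p(sprintf("%s.vcf", cohort)),
                           sprintf("%s_vcf", cohort)),
                  setNames(p(sprintf("%s_expression.tsv", cohort)),
                           sprintf("%s_expression", cohort)),
                  setNames(p(sprintf("%s_samples.tsv", cohort)),
                           sprintf("%s_samples", cohort)),
                  setNames(p(sprintf("%s_covariates.tsv", cohort)),
                           sprintf("%s_covariates", cohort)))
  }
  genes <- study$genes
  bed <- data.frame(chrom = genes$chrom, start = genes$tss - 1,
                    end = genes$tss, gene_id = genes$gene_id, score = 0,
                    strand = genes$strand)
  write.table(bed, p("genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(study$train$ground_truth, p("ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- c(manifest, gene_annotation = p("genes.bed"),
                ground_truth = p("ground_truth.tsv"))
  invisible(manifest)
}

#' Read a gene-annotation BED file
#'
#' BED is 0-based half-open; the TSS is taken strand-aware (interval start
#' for `+`, interval end for `-`) and converted to the 1-based coordinate
#' convention used for genotypes throughout.
#'
#' @param path BED file with columns chrom, start, end, gene_id, score,
#'   strand (no header).
#' @return data.frame `gene_id`, `chrom`, `tss` (1-based), `strand`.
#' @export
read_gene_annotation <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(bed)[1:4] <- c("chrom", "start", "end", "gene_id")
  strand <- if (ncol(bed) >= 6) bed[[6]] else "+"
  tss <- ifelse(strand == "-", bed$end, bed$start + 1)
  data.frame(gene_id = bed$gene_id, chrom = as.character(bed$chrom),
             tss = as.integer(tss), strand = strand,
             stringsAsFactors = FALSE)
}
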