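PIPELINE_STAGES <- c("simulate", "qc", "prep", "build", "predict",
                     "validate", "report")

PIPELINE_DEFAULTS <- list(
  out_dir = "sagex_run",
  seed = 1L,
  # simulate
  n_train = 566L, n_validate = 349L, frac_female = 0.345, n_genes = 20L,
  cis_snps_per_gene = 20L, n_causal = 3L, maf_range = c(0.05, 0.5),
  gene_class_mix = c(shared = 0.25, male_specific = 0.25,
                     female_specific = 0.25, null = 0.25),
  h2_male = 0.3, h2_female = 0.3, n_covariates = 5L, covar_var = 0.2,
  # qc
  maf_min = 0.01, imputation_r2_min = 0.8, missingness_max = 0.05,
  hwe_p_min = 1e-6, biallelic_snps_only = TRUE,
  # prep
  residualize_within_stratum = FALSE,
  # build
  window_bp = 1e6, alpha = 0.5, n_outer_folds = 10L, n_inner_folds = 10L,
  r2_min = 0.01, p_max = 0.05, strata = c("all", "male", "female"),
  # predict / validate
  zero_frac_max = 0.90, n_boot = 1000L, conf_level = 0.95,
  boot_all = FALSE)

#' Read and validate a pipeline configuration
#'
#' Reads a YAML key-value file, fills defaults, and rejects unknown keys.
#' All stage parameters (QC thresholds, normalization flags, elastic-net
#' settings, bootstrap settings) and the global seed live here; per-stage,
#' per-gene sub-seeds are derived from the global seed and gene id, so
#' per-gene results do not depend on which other genes are run.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @param overrides named list applied on top of the file.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- PIPELINE_DEFAULTS
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  user <- modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, user)
  if (!is.null(names(cfg$gene_class_mix)))
    cfg$gene_class_mix <- unlist(cfg$gene_class_mix)
  for (key in c("maf_min", "imputation_r2_min", "missingness_max",
                "hwe_p_min", "r2_min", "p_max", "zero_frac_max",
                "conf_level", "frac_female", "h2_male", "h2_female"))
    if (!is.null(cfg[[key]]) && (cfg[[key]] < 0 || cfg[[key]] > 1))
      stop(sprintf("config key '%s' must lie in [0, 1]", key))
  structure(cfg, class = "pipeline_config")
}

stage_dir <- function(cfg, stage) file.path(cfg$out_dir, stage)

write_manifest <- function(cfg, stage, inputs, outputs) {
  dir <- stage_dir(cfg, stage)
  hash_files <- function(paths) {
    paths <- unlist(paths)
    if (is.null(paths) || !length(paths)) return(setNames(list(), character(0)))
    paths <- paths[file.exists(paths)]
    if (!length(paths)) return(setNames(list(), character(0)))
    as.list(tools::md5sum(paths))
  }
  manifest <- list(
    stage = stage,
    seed = cfg$seed,
    config_hash = digest::digest(unclass(cfg)),
    package_version = as.character(packageVersion("sagex")),
    inputs = hash_files(inputs),
    outputs = hash_files(outputs))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Missing upstream artifacts abort with the name of the stage to run first;
# the producing stage is the artifact's directory name under out_dir.
require_upstream <- function(cfg, stage, files) {
  files <- unlist(files)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop(sprintf("stage '%s' is missing artifact '%s'; run stage '%s' first",
                 stage, missing[1], basename(dirname(missing[1]))),
         call. = FALSE)
}

artifact <- function(cfg, stage, ...) {
  files <- file.path(stage_dir(cfg, stage), c(...))
  attr(files, "produced_by") <- stage
  files
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic study fixtures), `qc` (variant filters on
#' both cohorts), `prep` (inverse normal transform + covariate
#' residualization), `build` (stratified elastic-net models, persisted as
#' PrediXcan-format databases), `predict` (genetically regulated expression
#' in the validation cohort per stratum), `validate` (within-sex regression,
#' classification, bootstrap), `report` (study summary tables), or `all`.
#' Every stage writes a `manifest.json` (input/output hashes, config hash,
#' seed, package version) into its output directory, and errors name the
#' stage to run first when an upstream artifact is absent.
#'
#' @param stage stage name or `all`.
#' @param config a `pipeline_config` from [read_pipeline_config()].
#' @return Invisibly, a character vector of the stage's output files.
#' @export
run_stage <- function(stage, config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(stage, "all")) {
    out <- lapply(PIPELINE_STAGES, run_stage, config = config)
    return(invisible(unlist(out)))
  }
  stage <- match.arg(stage, PIPELINE_STAGES)
  cfg <- config
  dir.create(stage_dir(cfg, stage), showWarnings = FALSE, recursive = TRUE)
  message(sprintf("[sagex] stage %s -> %s", stage, stage_dir(cfg, stage)))
  switch(stage,
    simulate = stage_simulate(cfg),
    qc = stage_qc(cfg),
    prep = stage_prep(cfg),
    build = stage_build(cfg),
    predict = stage_predict(cfg),
    validate = stage_validate(cfg),
    report = stage_report(cfg))
}

#' @rdname run_stage
#' @export
run_pipeline <- function(config) run_stage("all", config)

stage_simulate <- function(cfg) {
  sim_cfg <- simulation_config(
    n_train = cfg$n_train, n_validate = cfg$n_validate,
    frac_female = cfg$frac_female, n_genes = cfg$n_genes,
    cis_snps_per_gene = cfg$cis_snps_per_gene, n_causal = cfg$n_causal,
    maf_range = cfg$maf_range, gene_class_mix = cfg$gene_class_mix,
    h2_male = cfg$h2_male, h2_female = cfg$h2_female,
    n_covariates = cfg$n_covariates, covar_var = cfg$covar_var,
    seed = derive_seed(cfg$seed, "simulate"))
  manifest <- write_fixture_set(sim_cfg, stage_dir(cfg, "simulate"))
  write_manifest(cfg, "simulate", list(), as.list(manifest))
  invisible(unname(manifest))
}

qc_one <- function(cfg, vcf, out_vcf, log_path) {
  gm <- load_genotypes(vcf)
  spec <- variant_filter_spec(
    maf_min = cfg$maf_min, imputation_r2_min = cfg$imputation_r2_min,
    missingness_max = cfg$missingness_max, hwe_p_min = cfg$hwe_p_min,
    biallelic_snps_only = cfg$biallelic_snps_only)
  res <- filter_variants(gm, spec)
  write_vcf(res$genotypes, out_vcf)
  write.table(res$removed, log_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tally <- table(res$removed$reason)
  message(sprintf("  %s: %d -> %d variants (removed: %s)", basename(vcf),
                  ncol(gm$dosages), ncol(res$genotypes$dosages),
                  if (length(tally))
                    paste(names(tally), tally, sep = "=", collapse = ", ")
                  else "none"))
}

stage_qc <- function(cfg) {
  ins <- artifact(cfg, "simulate", c("train.vcf", "validate.vcf"))
  require_upstream(cfg, "qc", ins)
  outs <- file.path(stage_dir(cfg, "qc"),
                    c("train.vcf", "validate.vcf",
                      "train_removed.tsv", "validate_removed.tsv"))
  qc_one(cfg, ins[1], outs[1], outs[3])
  qc_one(cfg, ins[2], outs[2], outs[4])
  write_manifest(cfg, "qc", as.list(ins), as.list(outs))
  invisible(outs)
}

prep_one <- function(cfg, expr_path, covar_path, samples_path, out_path) {
  em <- read_expression_tsv(expr_path)
  covar <- read.delim(covar_path, check.names = FALSE)
  rownames(covar) <- covar$sample_id
  covar <- as.matrix(covar[, -1, drop = FALSE])
  samples <- read.delim(samples_path, stringsAsFactors = FALSE)
  sex_num <- as.numeric(factor(samples$sex, levels = c("female", "male")))
  covar <- cbind(covar, sex = sex_num[match(rownames(covar),
                                            samples$sample_id)])
  em <- inverse_normal_transform(expression_matrix(em$values, "filtered"))
  if (cfg$residualize_within_stratum) {
    # covariate effects re-estimated inside each sex, then recombined
    vals <- em$values
    for (s in c("male", "female")) {
      ids <- samples$sample_id[samples$sex == s]
      sub <- expression_matrix(vals[ids, , drop = FALSE], "int_normalized")
      vals[ids, ] <- suppressWarnings(
        residualize(sub, covar[ids, , drop = FALSE]))$values
    }
    em <- expression_matrix(vals, "residualized")
  } else {
    em <- residualize(em, covar)
  }
  write_expression_tsv(em, out_path)
  message(sprintf("  %s: %d genes, %d samples [%s]", basename(out_path),
                  length(em$gene_ids), length(em$sample_ids), em$state))
}

stage_prep <- function(cfg) {
  ins <- artifact(cfg, "simulate",
                  c("train_expression.tsv", "validate_expression.tsv",
                    "train_covariates.tsv", "validate_covariates.tsv",
                    "train_samples.tsv", "validate_samples.tsv"))
  require_upstream(cfg, "prep", ins)
  outs <- file.path(stage_dir(cfg, "prep"),
                    c("train_expression.tsv", "validate_expression.tsv"))
  prep_one(cfg, ins[1], ins[3], ins[5], outs[1])
  prep_one(cfg, ins[2], ins[4], ins[6], outs[2])
  write_manifest(cfg, "prep", as.list(ins), as.list(outs))
  invisible(outs)
}

read_sex_labels <- function(path) {
  samples <- read.delim(path, stringsAsFactors = FALSE)
  setNames(samples$sex, samples$sample_id)
}

stage_build <- function(cfg) {
  ins <- c(artifact(cfg, "qc", "train.vcf"),
           artifact(cfg, "prep", "train_expression.tsv"),
           artifact(cfg, "simulate", c("train_samples.tsv", "genes.bed")))
  require_upstream(cfg, "build", ins)
  gm <- load_genotypes(ins[1])
  em <- read_expression_tsv(ins[2])
  sex <- read_sex_labels(ins[3])
  annotation <- read_gene_annotation(ins[4])
  sets <- build_stratified_models(
    gm, em, sex, annotation,
    config = list(window_bp = cfg$window_bp, alpha = cfg$alpha,
                  n_outer_folds = cfg$n_outer_folds,
                  n_inner_folds = cfg$n_inner_folds, r2_min = cfg$r2_min,
                  p_max = cfg$p_max, seed = derive_seed(cfg$seed, "build"),
                  strata = cfg$strata))
  outs <- character(0)
  for (s in names(sets)) {
    db <- file.path(stage_dir(cfg, "build"), sprintf("models_%s.db", s))
    write_model_db(sets[[s]], db)
    outs <- c(outs, db)
    message(sprintf("  stratum %s: %d genes modeled (n = %d)", s,
                    length(sets[[s]]$models), sets[[s]]$n_samples))
  }
  summary_tsv <- file.path(stage_dir(cfg, "build"), "model_summary.tsv")
  write.table(summarize_study(sets)$model_performance, summary_tsv,
              sep = "\t", quote = FALSE, row.names = FALSE)
  outs <- c(outs, summary_tsv)
  write_manifest(cfg, "build", as.list(ins), as.list(outs))
  invisible(outs)
}

stage_predict <- function(cfg) {
  dbs <- file.path(stage_dir(cfg, "build"),
                   sprintf("models_%s.db", cfg$strata))
  ins <- c(artifact(cfg, "qc", "validate.vcf"),
           artifact(cfg, "build", basename(dbs)))
  require_upstream(cfg, "predict", ins)
  gm <- load_genotypes(ins[1])
  outs <- character(0)
  for (s in cfg$strata) {
    ms <- read_model_db(file.path(stage_dir(cfg, "build"),
                                  sprintf("models_%s.db", s)))
    if (!length(ms$models)) {
      message(sprintf("  stratum %s: no models; skipping", s))
      next
    }
    pred <- filter_uninformative(predict_expression(gm, ms),
                                 cfg$zero_frac_max)
    out <- file.path(stage_dir(cfg, "predict"),
                     sprintf("predicted_%s.tsv", s))
    stats <- file.path(stage_dir(cfg, "predict"),
                       sprintf("predicted_%s_stats.tsv", s))
    write_predicted_tsv(pred, out, stats)
    outs <- c(outs, out, stats)
    message(sprintf("  stratum %s: %d genes predicted", s,
                    ncol(pred$values)))
  }
  write_manifest(cfg, "predict", as.list(ins), as.list(outs))
  invisible(outs)
}

read_predicted_tsv <- function(path, stratum) {
  df <- read.delim(path, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$sample_id
  structure(list(values = values, stratum = stratum,
                 sample_ids = rownames(values), gene_ids = colnames(values),
                 coverage = NULL, zero_fraction = colMeans(abs(values) < 1e-12),
                 harmonization = NULL),
            class = "predicted_expression")
}

stage_validate <- function(cfg) {
  ins <- c(artifact(cfg, "predict",
                    c("predicted_all.tsv", "predicted_male.tsv",
                      "predicted_female.tsv")),
           artifact(cfg, "prep", "validate_expression.tsv"),
           artifact(cfg, "simulate", "validate_samples.tsv"))
  require_upstream(cfg, "validate", ins)
  observed <- read_expression_tsv(ins[4])
  sex <- read_sex_labels(ins[5])
  pred_all <- read_predicted_tsv(ins[1], "all")
  records <- list()
  for (s in c("male", "female")) {
    pred_s <- read_predicted_tsv(
      file.path(stage_dir(cfg, "predict"),
                sprintf("predicted_%s.tsv", s)), s)
    ids <- names(sex)[sex == s]
    records[[s]] <- validate_predictions(
      observed, pred_s, pred_all, sex = s, sample_ids = ids,
      n_boot = cfg$n_boot, conf_level = cfg$conf_level,
      seed = derive_seed(cfg$seed, "validate"), boot_all = cfg$boot_all)
    message(sprintf("  %s: %d genes tested, %d validated sex-specific", s,
                    nrow(records[[s]]), sum(records[[s]]$validated)))
  }
  out <- file.path(stage_dir(cfg, "validate"), "validation_records.tsv")
  write.table(do.call(rbind, records), out, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_manifest(cfg, "validate", as.list(ins), list(out))
  invisible(out)
}

stage_report <- function(cfg) {
  ins <- c(artifact(cfg, "build",
                    sprintf("models_%s.db", cfg$strata)),
           artifact(cfg, "validate", "validation_records.tsv"))
  require_upstream(cfg, "report", ins)
  sets <- setNames(lapply(cfg$strata, function(s)
    read_model_db(file.path(stage_dir(cfg, "build"),
                            sprintf("models_%s.db", s)))), cfg$strata)
  records <- read.delim(artifact(cfg, "validate", "validation_records.tsv"),
                        stringsAsFactors = FALSE)
  summary <- summarize_study(sets, records)
  dir <- stage_dir(cfg, "report")
  perf_tsv <- file.path(dir, "model_performance.tsv")
  overlap_tsv <- file.path(dir, "modeled_gene_overlap.tsv")
  validation_tsv <- file.path(dir, "validation_summary.tsv")
  write.table(summary$model_performance, perf_tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(region = names(summary$overlap),
                         n_genes = unname(summary$overlap)),
              overlap_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary$validation))
    write.table(summary$validation, validation_tsv, sep = "\t",
                quote = FALSE, row.names = FALSE)
  txt <- file.path(dir, "summary.txt")
  sink(txt); print(summary); sink()
  outs <- c(perf_tsv, overlap_tsv, validation_tsv, txt)
  write_manifest(cfg, "report", as.list(ins),
                 as.list(outs[file.exists(outs)]))
  invisible(outs)
}
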