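#' Regress observed expression on predicted expression
#'
#' Simple ordinary least squares of observed on an intercept plus predicted
#' expression. The reported R-squared is the squared Pearson correlation and
#' the p-value is the two-sided correlation-test p (identical to the slope
#' t-test). A zero-variance predictor makes the gene not testable.
#'
#' @param observed,predicted numeric vectors over the same samples (n >= 4).
#' @return List `beta` (slope), `pvalue`, `r2`, `n`.
#' @export
regress_observed_on_predicted <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must share samples")
  ok <- !is.na(observed) & !is.na(predicted)
  x <- predicted[ok]; y <- observed[ok]
  n <- length(x)
  if (n < 4) stop("need >= 4 samples")
  if (sd(x) == 0) stop("predictor has zero variance; gene not testable")
  beta <- cov(x, y) / var(x)
  if (sd(y) == 0) return(list(beta = 0, pvalue = 1, r2 = 0, n = n))
  ct <- cor.test(x, y)
  list(beta = beta, pvalue = ct$p.value, r2 = unname(ct$estimate)^2, n = n)
}

# Squared correlations for B bootstrap columns at once.
# y, x: n vectors; idx: n x B matrix of resampled row indices.
boot_r2 <- function(y, x, idx) {
  n <- nrow(idx)
  ym <- matrix(y[idx], n); xm <- matrix(x[idx], n)
  sy <- colSums(ym); sx <- colSums(xm)
  sxy <- colSums(xm * ym)
  sxx <- colSums(xm^2); syy <- colSums(ym^2)
  num <- n * sxy - sx * sy
  den <- (n * sxx - sx^2) * (n * syy - sy^2)
  r2 <- ifelse(den > 0, num^2 / den, NA_real_)
  r2
}

#' Bootstrap percentile interval for a difference in validation R-squared
#'
#' Resamples individuals with replacement, jointly across the observed
#' vector and both predictors (preserving their pairing), and computes the
#' difference `r2(observed, pred_sex) - r2(observed, pred_whole)` on each
#' resample; the interval is the percentile interval of those differences.
#' Resamples in which either predictor is constant are redrawn (up to 10
#' attempts each, then excluded with a note in the return value).
#'
#' @param observed,pred_sex,pred_whole numeric vectors over the same
#'   samples (n >= 10).
#' @param n_boot number of bootstrap resamples.
#' @param conf_level central interval mass.
#' @param seed integer seed for the resampling.
#' @return List `ci_low`, `ci_high`, `delta_r2` (point estimate), `n_boot`,
#'   `n_excluded` (degenerate resamples dropped after redraw attempts).
#' @export
bootstrap_delta_r2 <- function(observed, pred_sex, pred_whole,
                               n_boot = 1000, conf_level = 0.95, seed = 1L) {
  n <- length(observed)
  if (length(pred_sex) != n || length(pred_whole) != n)
    stop("all three vectors must share samples")
  if (n < 10) stop("need >= 10 samples to bootstrap")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n)
  delta <- boot_r2(observed, pred_sex, idx) - boot_r2(observed, pred_whole, idx)
  bad <- which(is.na(delta))
  attempt <- 0
  while (length(bad) && attempt < 10) {
    idx_new <- matrix(sample.int(n, n * length(bad), replace = TRUE), n)
    delta[bad] <- boot_r2(observed, pred_sex, idx_new) -
      boot_r2(observed, pred_whole, idx_new)
    bad <- bad[is.na(delta[bad])]
    attempt <- attempt + 1
  }
  n_excluded <- length(bad)
  delta_ok <- delta[!is.na(delta)]
  a <- (1 - conf_level) / 2
  ci <- unname(quantile(delta_ok, c(a, 1 - a), type = 7))
  point <- (if (sd(pred_sex) > 0) cor(observed, pred_sex)^2 else NA_real_) -
    (if (sd(pred_whole) > 0) cor(observed, pred_whole)^2 else NA_real_)
  list(ci_low = ci[1], ci_high = ci[2], delta_r2 = point,
       n_boot = length(delta_ok), n_excluded = n_excluded)
}

#' Classify a gene's validation outcome
#'
#' Applies the validation criteria to the within-sex regressions of observed
#' expression on sex-specific and on whole-sample predicted expression:
#' \itemize{
#'   \item `validated_sex_specific` — sex-specific prediction positively and
#'     significantly associated (beta > 0, p < 0.05) and sex-specific R2
#'     strictly above whole-sample R2;
#'   \item `validated_whole_sample` — the whole-sample counterpart (beta > 0,
#'     p < 0.05 on the whole-sample prediction, whole-sample R2 strictly
#'     above);
#'   \item `direction_consistent_only` — the relevant comparison's better
#'     predictor has beta > 0 but p >= 0.05;
#'   \item `not_validated` — everything else.
#' }
#' Ties in R2 validate neither category. When a bootstrap interval is
#' supplied, `significant` flags whether it excludes zero.
#'
#' @param record_sex,record_whole outputs of
#'   [regress_observed_on_predicted()] for the sex-specific and whole-sample
#'   predictions within one sex.
#' @param boot_ci optional output of [bootstrap_delta_r2()].
#' @return List `category` and `significant` (NA without `boot_ci`).
#' @export
classify_gene <- function(record_sex, record_whole, boot_ci = NULL) {
  category <- if (record_sex$pvalue < 0.05 && record_sex$beta > 0 &&
                  record_sex$r2 > record_whole$r2) {
    "validated_sex_specific"
  } else if (record_whole$pvalue < 0.05 && record_whole$beta > 0 &&
             record_whole$r2 > record_sex$r2) {
    "validated_whole_sample"
  } else {
    better <- if (record_sex$r2 >= record_whole$r2) record_sex else record_whole
    if (better$beta > 0 && better$pvalue >= 0.05)
      "direction_consistent_only" else "not_validated"
  }
  significant <- if (is.null(boot_ci)) NA else
    (boot_ci$ci_low > 0 || boot_ci$ci_high < 0)
  list(category = category, significant = significant)
}

#' Validate sex-specific against whole-sample predictions within one sex
#'
#' For every gene present in both prediction sets, runs the within-sex
#' regressions, classifies the gene, and (for genes classified
#' `validated_sex_specific`, or all genes with `boot_all = TRUE`) bootstraps
#' the R-squared difference.
#'
#' @param observed an [expression_matrix()] of observed expression for the
#'   target-sex samples.
#' @param pred_sex,pred_whole `predicted_expression` objects (already
#'   restricted or restrictable to the target-sex samples).
#' @param sex one of `male`, `female` (recorded in the output).
#' @param sample_ids samples of the target sex to use.
#' @param n_boot,conf_level bootstrap parameters.
#' @param seed integer; per-gene bootstrap seeds derive from it.
#' @param boot_all bootstrap every testable gene, not only validated ones.
#' @return data.frame, one row per testable gene: `gene_id`, `stratum`,
#'   `beta`, `pvalue`, `r2_sex`, `r2_whole`, `delta_r2`, `ci_low`,
#'   `ci_high`, `n_boot`, `validated`, `significant`, `category`.
#' @export
validate_predictions <- function(observed, pred_sex, pred_whole, sex,
                                 sample_ids = NULL, n_boot = 1000,
                                 conf_level = 0.95, seed = 1L,
                                 boot_all = FALSE) {
  stopifnot(inherits(observed, "expression_matrix"))
  ids <- sample_ids %||% observed$sample_ids
  ids <- Reduce(intersect, list(ids, rownames(pred_sex$values),
                                rownames(pred_whole$values),
                                observed$sample_ids))
  genes <- Reduce(intersect, list(colnames(pred_sex$values),
                                  colnames(pred_whole$values),
                                  observed$gene_ids))
  rows <- list()
  for (gene in genes) {
    y <- observed$values[ids, gene]
    xs <- pred_sex$values[ids, gene]
    xw <- pred_whole$values[ids, gene]
    if (sd(xs) == 0 || sd(xw) == 0) next  # not testable
    rs <- regress_observed_on_predicted(y, xs)
    rw <- regress_observed_on_predicted(y, xw)
    cls <- classify_gene(rs, rw)
    ci <- list(ci_low = NA_real_, ci_high = NA_real_, n_boot = 0L)
    if (boot_all || cls$category == "validated_sex_specific") {
      ci <- bootstrap_delta_r2(y, xs, xw, n_boot = n_boot,
                               conf_level = conf_level,
                               seed = derive_seed(seed, "boot", sex, gene))
      cls <- classify_gene(rs, rw, ci)
    }
    rows[[gene]] <- data.frame(
      gene_id = gene, stratum = sex, beta = rs$beta, pvalue = rs$pvalue,
      r2_sex = rs$r2, r2_whole = rw$r2, delta_r2 = rs$r2 - rw$r2,
      ci_low = ci$ci_low, ci_high = ci$ci_high, n_boot = ci$n_boot,
      validated = cls$category == "validated_sex_specific",
      significant = if (is.na(cls$significant)) NA else cls$significant,
      category = cls$category, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), stratum = character(),
               beta = numeric(), pvalue = numeric(), r2_sex = numeric(),
               r2_whole = numeric(), delta_r2 = numeric(),
               ci_low = numeric(), ci_high = numeric(), n_boot = integer(),
               validated = logical(), significant = logical(),
               category = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize model sets and validation records
#'
#' Produces the study-level report: per-stratum model counts with mean,
#' standard error and range of cross-validated R-squared; the three-way
#' overlap partition of modeled gene sets; and the distribution of the
#' sex-specific-minus-whole-sample R-squared difference with per-sex means
#' and the fraction of genes improving by more than 0.2.
#'
#' @param model_sets named list of `model_set`s (`all`, `male`, `female` —
#'   any subset).
#' @param validation_records data.frame from [validate_predictions()]
#'   (rows for both sexes may be concatenated), or NULL.
#' @return A `study_summary`: `model_performance` (data.frame), `overlap`
#'   (named counts partitioning modeled genes), `delta_r2` (per-sex mean,
#'   fraction > 0.2, and the delta values), `validation` (per-sex counts).
#' @export
summarize_study <- function(model_sets, validation_records = NULL) {
  perf <- do.call(rbind, lapply(names(model_sets), function(s) {
    ms <- model_sets[[s]]
    r2 <- vapply(ms$models, `[[`, numeric(1), "cv_r2")
    if (!length(r2))
      return(data.frame(stratum = s, n_samples = ms$n_samples, n_genes = 0L,
                        mean_r2 = NA_real_, se_r2 = NA_real_,
                        min_r2 = NA_real_, max_r2 = NA_real_))
    data.frame(stratum = s, n_samples = ms$n_samples,
               n_genes = length(r2), mean_r2 = mean(r2),
               se_r2 = sd(r2) / sqrt(length(r2)),
               min_r2 = min(r2), max_r2 = max(r2))
  }))
  rownames(perf) <- NULL

  sets <- lapply(model_sets, function(ms) names(ms$models))
  g_all <- sets$all %||% character(0)
  g_m <- sets$male %||% character(0)
  g_f <- sets$female %||% character(0)
  overlap <- c(
    all_only = length(setdiff(g_all, union(g_m, g_f))),
    male_only = length(setdiff(g_m, union(g_all, g_f))),
    female_only = length(setdiff(g_f, union(g_all, g_m))),
    all_male = length(setdiff(intersect(g_all, g_m), g_f)),
    all_female = length(setdiff(intersect(g_all, g_f), g_m)),
    male_female = length(setdiff(intersect(g_m, g_f), g_all)),
    all_three = length(intersect(intersect(g_all, g_m), g_f)),
    total = length(unique(c(g_all, g_m, g_f))))

  delta <- validation <- NULL
  if (!is.null(validation_records) && nrow(validation_records)) {
    vr <- validation_records
    delta <- lapply(split(vr, vr$stratum), function(d) {
      list(mean = mean(d$delta_r2), frac_gt_0.2 = mean(d$delta_r2 > 0.2),
           values = d$delta_r2)
    })
    validation <- do.call(rbind, lapply(split(vr, vr$stratum), function(d)
      data.frame(stratum = d$stratum[1], n_tested = nrow(d),
                 n_validated = sum(d$validated),
                 n_significant = sum(d$significant %in% TRUE),
                 mean_r2_validated = if (any(d$validated))
                   mean(d$r2_sex[d$validated]) else NA_real_)))
    rownames(validation) <- NULL
  }
  structure(list(model_performance = perf, overlap = overlap,
                 delta_r2 = delta, validation = validation),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Model characteristics\n")
  perf <- x$model_performance
  cat(sprintf("  %-8s n=%4s  genes=%5d  mean R2 %s (SE %s)  range %s-%s\n",
              perf$stratum, perf$n_samples, perf$n_genes,
              formatC(perf$mean_r2, format = "f", digits = 3),
              formatC(perf$se_r2, format = "f", digits = 3),
              formatC(perf$min_r2, format = "f", digits = 3),
              formatC(perf$max_r2, format = "f", digits = 3)), sep = "")
  cat("Modeled-gene overlap: ",
      paste(names(x$overlap), x$overlap, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$validation)) {
    cat("Validation\n")
    v <- x$validation
    cat(sprintf("  %-8s tested=%4d validated=%4d significant=%3d\n",
                v$stratum, v$n_tested, v$n_validated, v$n_significant),
        sep = "")
  }
  invisible(x)
}
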