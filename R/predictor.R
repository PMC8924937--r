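#' Harmonize a model variant with a cohort variant
#'
#' Decides how a model SNP's effect allele maps onto the cohort's dosage
#' coding at the same site: `match` when the model's (effect, other) alleles
#' equal the cohort's (alt, ref); `flip` when they are swapped, in which case
#' the prediction uses `2 - dosage`; `ambiguous_drop` for strand-ambiguous
#' pairs (A/T, C/G), which cannot be oriented without frequency information
#' and are dropped conservatively; `mismatch_drop` otherwise.
#'
#' @param effect_allele,other_allele model alleles (effect = the allele the
#'   weight counts).
#' @param cohort_ref,cohort_alt cohort VCF alleles (dosage counts alt).
#' @return One of `"match"`, `"flip"`, `"ambiguous_drop"`, `"mismatch_drop"`.
#' @export
harmonize_alleles <- function(effect_allele, other_allele,
                              cohort_ref, cohort_alt) {
  pair <- sort(c(effect_allele, other_allele))
  if (identical(pair, c("A", "T")) || identical(pair, c("C", "G")))
    return("ambiguous_drop")
  if (effect_allele == cohort_alt && other_allele == cohort_ref)
    return("match")
  if (effect_allele == cohort_ref && other_allele == cohort_alt)
    return("flip")
  "mismatch_drop"
}

#' Predict genetically regulated expression in an independent cohort
#'
#' For each gene, predicted expression is the weighted sum of harmonized
#' alternate-allele dosages over the model's SNPs. Model SNPs absent from
#' the cohort contribute zero and lower the gene's coverage (the
#' uninformativeness filter downstream catches genes with no usable SNPs);
#' flipped SNPs use `2 - dosage`; ambiguous or mismatching SNPs are dropped
#' and logged. Missing dosages are mean-imputed within variant.
#'
#' @param genotypes cohort [genotype_matrix()] (post-QC).
#' @param ms a `model_set` whose weights carry allele columns.
#' @return A `predicted_expression` object: `values` (samples x genes),
#'   `stratum`, `coverage` and `zero_fraction` (named per gene), and
#'   `harmonization` (data.frame log: gene, variant, decision).
#' @export
predict_expression <- function(genotypes, ms) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(ms, "model_set"))
  if (!length(ms$models)) stop("empty model set")
  d <- genotypes$dosages
  if (anyNA(d))
    for (j in which(colSums(is.na(d)) > 0))
      d[is.na(d[, j]), j] <- mean(d[, j], na.rm = TRUE)
  v <- genotypes$variants
  n <- nrow(d)
  genes <- names(ms$models)
  values <- matrix(0, n, length(genes),
                   dimnames = list(rownames(d), genes))
  coverage <- setNames(numeric(length(genes)), genes)
  log_rows <- list()
  for (gene in genes) {
    w <- ms$models[[gene]]$weights
    used <- 0
    pred <- numeric(n)
    for (i in seq_len(nrow(w))) {
      j <- match(w$variant_id[i], v$id)
      if (is.na(j)) {
        decision <- "absent"
      } else {
        decision <- harmonize_alleles(w$effect_allele[i], w$other_allele[i],
                                      v$ref[j], v$alt[j])
        if (decision == "match") {
          pred <- pred + w$weight[i] * d[, j]
          used <- used + 1
        } else if (decision == "flip") {
          pred <- pred + w$weight[i] * (2 - d[, j])
          used <- used + 1
        }
      }
      log_rows[[length(log_rows) + 1]] <-
        data.frame(gene = gene, variant_id = w$variant_id[i],
                   decision = decision, stringsAsFactors = FALSE)
    }
    values[, gene] <- pred
    coverage[gene] <- if (nrow(w)) used / nrow(w) else 0
  }
  structure(list(
    values = values, stratum = ms$stratum,
    sample_ids = rownames(d), gene_ids = genes,
    coverage = coverage,
    zero_fraction = colMeans(abs(values) < 1e-12),
    harmonization = if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(gene = character(), variant_id = character(),
                 decision = character())),
    class = "predicted_expression")
}

#' @export
print.predicted_expression <- function(x, ...) {
  cat(sprintf("predicted_expression [%s]: %d samples x %d genes\n",
              x$stratum, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Drop genes whose prediction is uninformative
#'
#' A gene is removed when strictly more than `zero_frac_max` of its
#' predicted values are zero (|value| < 1e-12): such predictions carry no
#' information about the gene (typically all model SNPs were absent or
#' monomorphic in the cohort). A gene at exactly the threshold is kept.
#'
#' @param predicted a `predicted_expression`.
#' @param zero_frac_max strict threshold on the per-gene zero fraction.
#' @return A filtered `predicted_expression`.
#' @export
filter_uninformative <- function(predicted, zero_frac_max = 0.90) {
  stopifnot(inherits(predicted, "predicted_expression"))
  keep <- predicted$zero_fraction <= zero_frac_max
  structure(list(
    values = predicted$values[, keep, drop = FALSE],
    stratum = predicted$stratum,
    sample_ids = predicted$sample_ids,
    gene_ids = predicted$gene_ids[keep],
    coverage = predicted$coverage[keep],
    zero_fraction = predicted$zero_fraction[keep],
    harmonization = predicted$harmonization),
    class = "predicted_expression")
}

#' Write predicted expression to TSV
#'
#' @param predicted a `predicted_expression`.
#' @param path output TSV (samples x genes, `sample_id` first column).
#' @param stats_path optional TSV for per-gene coverage and zero fraction.
#' @return `path`, invisibly.
#' @export
write_predicted_tsv <- function(predicted, path, stats_path = NULL) {
  df <- data.frame(sample_id = predicted$sample_ids, predicted$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(stats_path))
    write.table(data.frame(gene_id = predicted$gene_ids,
                           coverage = unname(predicted$coverage),
                           zero_fraction = unname(predicted$zero_fraction)),
                stats_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
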