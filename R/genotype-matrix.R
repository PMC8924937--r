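#' Genotype dosage matrix with variant metadata
#'
#' Container for imputed genotype dosages: a samples x variants matrix of
#' alternate-allele dosages in \[0, 2\] (NA for missing) plus one metadata row
#' per variant. Minor allele frequency and per-variant missingness are
#' recomputed from the dosages at construction so they always reflect the
#' current sample set.
#'
#' @param dosages numeric matrix, samples x variants, values in \[0, 2\] or NA.
#'   Row names are sample ids, column names variant ids.
#' @param variants data.frame with one row per dosage column: `id`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`, and optionally `imputation_r2` and
#'   `biallelic_snp` (logical; defaults to TRUE).
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `variants` (with `maf` and `missingness` columns filled in) and
#'   `sample_ids`.
#' @export
genotype_matrix <- function(dosages, variants) {
  stopifnot(is.matrix(dosages), nrow(variants) == ncol(dosages))
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("sample_", seq_len(nrow(dosages)))
  colnames(dosages) <- variants$id
  if (anyDuplicated(variants$id))
    stop("variant ids must be unique")
  if (length(dosages) && any(!is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  }
  variants$imputation_r2 <- variants$imputation_r2 %||% rep(NA_real_, nrow(variants))
  variants$biallelic_snp <- variants$biallelic_snp %||% rep(TRUE, nrow(variants))
  variants$maf <- vapply(seq_len(ncol(dosages)), function(j) {
    d <- dosages[, j]
    if (all(is.na(d))) NA_real_ else compute_maf(d)
  }, numeric(1))
  variants$missingness <- colMeans(is.na(dosages))
  structure(
    list(dosages = dosages, variants = variants,
         sample_ids = rownames(dosages)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  MAF range: %.4f - %.4f\n",
              min(x$variants$maf, na.rm = TRUE),
              max(x$variants$maf, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param gm a [genotype_matrix()].
#' @param samples character vector of sample ids to keep (in that order), or
#'   NULL to keep all.
#' @param variants character vector of variant ids to keep, or NULL.
#' @return A new `genotype_matrix`; MAF and missingness are recomputed on the
#'   retained samples.
#' @export
subset_genotypes <- function(gm, samples = NULL, variants = NULL) {
  d <- gm$dosages
  v <- gm$variants
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(d))
    if (length(missing))
      stop("unknown sample id(s): ", paste(missing, collapse = ", "))
    d <- d[samples, , drop = FALSE]
  }
  if (!is.null(variants)) {
    keep <- match(variants, v$id)
    if (anyNA(keep))
      stop("unknown variant id(s): ",
           paste(variants[is.na(keep)], collapse = ", "))
    d <- d[, keep, drop = FALSE]
    v <- v[keep, , drop = FALSE]
  }
  genotype_matrix(d, v)
}

#' Minor allele frequency of one variant
#'
#' Alternate-allele frequency is the mean dosage over non-missing samples
#' divided by 2; the MAF folds it at 0.5 (`min(f, 1 - f)`). Missing dosages
#' are excluded, not imputed: per-variant missingness is a separate QC filter.
#'
#' @param dosages numeric vector of dosages in \[0, 2\], NA for missing.
#' @return MAF in \[0, 0.5\].
#' @export
#' @examples
#' compute_maf(c(0, 1, 2, 1))  # alt frequency 0.5 -> MAF 0.5
#' compute_maf(c(2, 2, 2, 2))  # alt frequency 1 folds to 0
compute_maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop("all dosages missing; MAF undefined")
  f <- mean(d) / 2
  min(f, 1 - f)
}

#' Hardy-Weinberg equilibrium test from hard genotype counts
#'
#' One-degree-of-freedom chi-square goodness-of-fit of the observed genotype
#' counts against the counts expected from the allele frequencies. Intended
#' for hard calls obtained by rounding dosages (Hardy-Weinberg is undefined
#' on continuous dosages). Monomorphic variants fit trivially (p = 1).
#'
#' @param n_ref_hom,n_het,n_alt_hom non-negative genotype counts.
#' @return Two-sided p-value.
#' @export
#' @examples
#' compute_hwe_p(25, 50, 25)   # exact equilibrium at f = 0.5 -> p = 1
#' compute_hwe_p(50, 0, 50)    # total heterozygote deficit -> p << 1e-6
compute_hwe_p <- function(n_ref_hom, n_het, n_alt_hom) {
  counts <- c(n_ref_hom, n_het, n_alt_hom)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("no genotypes; HWE undefined")
  p_alt <- (n_het + 2 * n_alt_hom) / (2 * n)
  if (p_alt == 0 || p_alt == 1) return(1)
  expected <- n * c((1 - p_alt)^2, 2 * p_alt * (1 - p_alt), p_alt^2)
  chisq <- sum((counts - expected)^2 / expected)
  pchisq(chisq, df = 1, lower.tail = FALSE)
}
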