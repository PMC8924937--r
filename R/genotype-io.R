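#' Load genotype dosages from a VCF file
#'
#' Reads a VCF 4.2 file (plain or gzipped) into a [genotype_matrix()].
#' Dosages are taken from the `DS` FORMAT field when present, otherwise
#' computed from `GT` as the count of alternate alleles. Multi-allelic
#' records and indels are kept but flagged (`biallelic_snp = FALSE`) so that
#' [filter_variants()] can remove them; the `R2` INFO tag (post-imputation
#' quality) is parsed into `imputation_r2`.
#'
#' @param vcf_path path to a VCF file.
#' @param sample_subset character vector of sample ids to keep, in the
#'   desired row order; NULL keeps all samples in file order.
#' @return A [genotype_matrix()].
#' @export
load_genotypes <- function(vcf_path, sample_subset = NULL) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_var <- nrow(fix)
  if (n_var == 0) stop("VCF contains no variant records: ", vcf_path)
  samples <- colnames(vcf@gt)[-1]
  if (is.null(sample_subset)) sample_subset <- samples
  unknown <- setdiff(sample_subset, samples)
  if (length(unknown))
    stop("sample id(s) not in VCF: ", paste(unknown, collapse = ", "))

  fmt_has_ds <- grepl("(^|:)DS(:|$)", vcf@gt[, "FORMAT"])
  dos <- matrix(NA_real_, nrow = n_var, ncol = length(samples),
                dimnames = list(NULL, samples))
  if (any(fmt_has_ds)) {
    ds <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE))
    dos[fmt_has_ds, ] <- ds[fmt_has_ds, , drop = FALSE]
  }
  if (any(!fmt_has_ds)) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    alt_count <- function(g) {
      alleles <- strsplit(g, "[/|]")
      vapply(alleles, function(a) {
        if (any(a == "." | is.na(a))) return(NA_real_)
        sum(a != "0")
      }, numeric(1))
    }
    gt_rows <- which(!fmt_has_ds)
    for (i in gt_rows) dos[i, ] <- alt_count(gt[i, ])
  }
  bad <- which(!is.na(dos) & (dos < 0 | dos > 2), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("malformed dosage at variant record %d (id %s): %s",
                 bad[1, 1], fix$ID[bad[1, 1]], dos[bad[1, , drop = FALSE]]))

  r2 <- rep(NA_real_, n_var)
  has_info <- !is.na(fix$INFO)
  m <- regmatches(fix$INFO, regexec("(?:^|;)R2=([0-9eE.+-]+)", fix$INFO))
  got <- has_info & lengths(m) == 2
  r2[got] <- as.numeric(vapply(m[got], `[`, character(1), 2))

  is_snp <- !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  ids <- fix$ID
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste(fix$CHROM[blank], fix$POS[blank], sep = "_")

  variants <- data.frame(
    id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    imputation_r2 = r2, biallelic_snp = is_snp,
    stringsAsFactors = FALSE)
  genotype_matrix(t(dos[, sample_subset, drop = FALSE]), variants)
}

#' Write a genotype matrix as a VCF file
#'
#' Emits VCF 4.2 in the post-imputation dialect the QC filters expect:
#' `GT:DS` FORMAT (hard calls rounded from dosage, plus the dosage itself)
#' and an `R2` INFO tag carrying imputation quality. Missing dosages become
#' `./.:.`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  d <- gm$dosages
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t"))
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(j) {
    ds <- d[, j]
    hard <- pmin(pmax(round(ds), 0), 2)
    field <- ifelse(is.na(ds), "./.:.",
                    paste0(gt_codes[hard + 1], ":", formatC(ds, format = "g")))
    info <- if (is.na(v$imputation_r2[j])) "." else
      sprintf("R2=%s", formatC(v$imputation_r2[j], format = "g"))
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            info, "GT:DS", field), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Variant QC filter thresholds
#'
#' Threshold semantics follow the conventional printed inequalities of
#' post-imputation QC exactly: variants are *excluded* when MAF `<` `maf_min`,
#' missingness `>` `missingness_max`, or Hardy-Weinberg p `<` `hwe_p_min`;
#' they are *retained* only when imputation R-squared `>` `imputation_r2_min`
#' (so a variant at exactly the threshold is dropped). Set a threshold to
#' NULL to disable that rule.
#'
#' @param maf_min minimum minor allele frequency (exclude below).
#' @param imputation_r2_min imputation quality; keep only strictly above.
#' @param missingness_max maximum fraction missing (exclude above).
#' @param hwe_p_min Hardy-Weinberg p-value floor (exclude below).
#' @param biallelic_snps_only drop multi-allelic records and indels.
#' @return A `variant_filter_spec` object.
#' @export
variant_filter_spec <- function(maf_min = 0.01, imputation_r2_min = NULL,
                                missingness_max = NULL, hwe_p_min = NULL,
                                biallelic_snps_only = TRUE) {
  for (th in c(maf_min, imputation_r2_min, missingness_max, hwe_p_min))
    if (!is.null(th) && (th < 0 || th > 1))
      stop("filter thresholds must lie in [0, 1]")
  structure(list(maf_min = maf_min, imputation_r2_min = imputation_r2_min,
                 missingness_max = missingness_max, hwe_p_min = hwe_p_min,
                 biallelic_snps_only = isTRUE(biallelic_snps_only)),
            class = "variant_filter_spec")
}

#' Apply variant QC filters
#'
#' Each variant is checked against the rules of a [variant_filter_spec()] in
#' a fixed order (MAF, imputation R2, missingness, Hardy-Weinberg,
#' biallelic-SNP); the removal log records the first failing rule per
#' removed variant. Hardy-Weinberg is tested on hard calls obtained by
#' rounding dosages to the nearest integer.
#'
#' @param gm a [genotype_matrix()].
#' @param spec a [variant_filter_spec()].
#' @return A list with `genotypes` (the filtered [genotype_matrix()]; may
#'   have zero variants) and `removed` (data.frame `variant_id`, `reason`).
#' @export
filter_variants <- function(gm, spec) {
  stopifnot(inherits(spec, "variant_filter_spec"))
  v <- gm$variants
  reason <- rep(NA_character_, nrow(v))
  fail <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  if (!is.null(spec$maf_min))
    fail(v$maf < spec$maf_min, "maf")
  if (!is.null(spec$imputation_r2_min))
    fail(!(v$imputation_r2 > spec$imputation_r2_min), "imputation_r2")
  if (!is.null(spec$missingness_max))
    fail(v$missingness > spec$missingness_max, "missingness")
  if (!is.null(spec$hwe_p_min)) {
    todo <- which(is.na(reason))
    if (length(todo)) {
      hwe_p <- vapply(todo, function(j) {
        hard <- round(gm$dosages[, j])
        hard <- hard[!is.na(hard)]
        compute_hwe_p(sum(hard == 0), sum(hard == 1), sum(hard == 2))
      }, numeric(1))
      full <- rep(NA, nrow(v)); full[todo] <- hwe_p < spec$hwe_p_min
      fail(full, "hwe")
    }
  }
  if (spec$biallelic_snps_only)
    fail(!v$biallelic_snp, "not_biallelic_snp")

  keep <- is.na(reason)
  removed <- data.frame(variant_id = v$id[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  out <- list(
    genotypes = genotype_matrix(gm$dosages[, keep, drop = FALSE],
                                v[keep, setdiff(names(v), c("maf", "missingness")),
                                  drop = FALSE]),
    removed = removed)
  out
}
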