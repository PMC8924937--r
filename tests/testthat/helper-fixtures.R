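# Small in-code fixtures shared across test files.

tiny_config <- function(seed = 11L, ...) {
  args <- modifyList(
    list(n_train = 120L, n_validate = 80L, frac_female = 0.5,
         n_genes = 8L, cis_snps_per_gene = 10L, n_causal = 2L,
         seed = seed),
    list(...))
  do.call(simulation_config, args)
}

# Hand-built genotype matrix: explicit dosages and variant metadata.
toy_genotypes <- function(dosages, chrom = "1", pos = NULL, ref = "A",
                          alt = "G", imputation_r2 = 1) {
  p <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(p) * 100L
  genotype_matrix(dosages, data.frame(
    id = colnames(dosages) %||% paste0("v", seq_len(p)),
    chrom = chrom, pos = as.integer(pos),
    ref = rep_len(ref, p), alt = rep_len(alt, p),
    imputation_r2 = rep_len(imputation_r2, p),
    biallelic_snp = TRUE, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write VCF lines to a temp file and return the path.
write_vcf_lines <- function(body, samples = c("S1", "S2", "S3"),
                            format = "GT:DS") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  path <- tempfile(fileext = ".vcf")
  writeLines(c(header, body), path)
  path
}
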