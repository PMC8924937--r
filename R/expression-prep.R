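EXPR_STATES <- c("raw", "filtered", "quantile_normalized", "int_normalized",
                 "residualized")

#' Expression matrix with a processing-state tag
#'
#' Samples x genes matrix of expression values carrying a state tag that
#' records how far along the processing pipeline (raw -> filtered ->
#' quantile_normalized -> int_normalized -> residualized) the values are.
#' State transitions only move forward; each processing function checks the
#' tag so stages cannot be applied out of order.
#'
#' @param values numeric matrix, samples x genes, with sample ids as row
#'   names and gene ids as column names.
#' @param state one of `raw`, `filtered`, `quantile_normalized`,
#'   `int_normalized`, `residualized`.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, state = "raw") {
  stopifnot(is.matrix(values))
  state <- match.arg(state, EXPR_STATES)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("gene_", seq_len(ncol(values)))
  structure(list(values = values, sample_ids = rownames(values),
                 gene_ids = colnames(values), state = state),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d genes [%s]\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

advance_state <- function(em, from, to) {
  if (!em$state %in% from)
    stop(sprintf("expression state is '%s'; this stage requires %s",
                 em$state, paste(sQuote(from), collapse = " or ")))
  to
}

#' Keep genes expressed above thresholds in enough samples
#'
#' A gene is retained when, in at least `min_samples` samples, its abundance
#' is strictly greater than `rpkm_min` RPKM *and* its read count is strictly
#' greater than `reads_min`. The defaults (10 samples, 0.1 RPKM, 5 reads)
#' are the standard bulk RNA-seq expression filter used ahead of eQTL model
#' building.
#'
#' @param rpkm samples x genes RPKM matrix (or raw [expression_matrix()]).
#' @param counts samples x genes read-count matrix of identical shape.
#' @param min_samples inclusive sample-count threshold.
#' @param rpkm_min,reads_min strict per-sample thresholds.
#' @return A `filtered` [expression_matrix()] holding the RPKM values of the
#'   retained genes.
#' @export
filter_expressed_genes <- function(rpkm, counts, min_samples = 10,
                                   rpkm_min = 0.1, reads_min = 5) {
  if (inherits(rpkm, "expression_matrix")) rpkm <- rpkm$values
  if (inherits(counts, "expression_matrix")) counts <- counts$values
  if (!identical(dim(rpkm), dim(counts)))
    stop("rpkm and counts must have identical dimensions")
  ok <- colSums(rpkm > rpkm_min & counts > reads_min) >= min_samples
  expression_matrix(rpkm[, ok, drop = FALSE], state = "filtered")
}

#' Quantile normalize samples to the average empirical distribution
#'
#' The reference distribution is the mean of the sorted per-sample vectors
#' (the average k-th order statistic across samples). Each sample's values
#' are replaced by the reference values at their within-sample ranks; tied
#' values receive the mean of the reference values at the tied positions.
#' After normalization every sample has exactly the reference distribution.
#'
#' @param em a `filtered` [expression_matrix()].
#' @return A `quantile_normalized` [expression_matrix()].
#' @export
quantile_normalize_to_average <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  to <- advance_state(em, c("filtered"), "quantile_normalized")
  x <- em$values
  if (nrow(x) < 2) stop("quantile normalization requires >= 2 samples")
  if (anyNA(x)) stop("missing expression values are not supported")
  sorted <- apply(x, 1, sort)            # genes x samples (each col sorted)
  ref <- rowMeans(sorted)
  cs <- c(0, cumsum(ref))
  for (i in seq_len(nrow(x))) {
    lo <- rank(x[i, ], ties.method = "min")
    hi <- rank(x[i, ], ties.method = "max")
    x[i, ] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  expression_matrix(x, state = to)
}

#' Rank-based inverse normal transform, per gene
#'
#' Within each gene, values are replaced by standard-normal quantiles of
#' their ranks, `qnorm(rank / (n + 1))`, with average ranks for ties. The
#' `rank/(n+1)` offset (rather than a Blom-type correction) is the
#' convention of the standard eQTL expression pipeline.
#'
#' @param em a `quantile_normalized` (or, for standalone use, `filtered` or
#'   `raw`) [expression_matrix()].
#' @return An `int_normalized` [expression_matrix()].
#' @export
inverse_normal_transform <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  to <- advance_state(em, c("raw", "filtered", "quantile_normalized"),
                      "int_normalized")
  x <- em$values
  n <- nrow(x)
  if (n < 3) stop("inverse normal transform requires >= 3 samples")
  for (j in seq_len(ncol(x)))
    x[, j] <- qnorm(rank(x[, j], ties.method = "average") / (n + 1))
  expression_matrix(x, state = to)
}

#' Residualize expression on covariates
#'
#' Per gene, values are replaced by ordinary-least-squares residuals of the
#' values on an intercept plus the covariate columns. Constant covariate
#' columns are dropped with a warning (this is what makes, e.g., sex a valid
#' covariate even in a single-sex stratum); a design that is rank-deficient
#' after cleaning is an error.
#'
#' @param em an `int_normalized` (or earlier non-raw) [expression_matrix()].
#' @param covariates numeric matrix or data.frame, samples x covariates, with
#'   sample ids as row names matching `em`; NULL for intercept-only
#'   (mean-centering).
#' @return A `residualized` [expression_matrix()].
#' @export
residualize <- function(em, covariates = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  to <- advance_state(em, c("filtered", "quantile_normalized", "int_normalized"),
                      "residualized")
  n <- nrow(em$values)
  design <- matrix(1, n, 1, dimnames = list(em$sample_ids, "(Intercept)"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("covariates and expression must share samples")
    if (!is.null(rownames(covariates))) {
      if (!setequal(rownames(covariates), em$sample_ids))
        stop("covariates and expression must share sample ids")
      covariates <- covariates[em$sample_ids, , drop = FALSE]
    }
    keep <- apply(covariates, 2, function(c) sd(c) > 0)
    if (any(!keep))
      warning("dropping constant covariate column(s): ",
              paste(colnames(covariates)[!keep], collapse = ", "))
    design <- cbind(design, covariates[, keep, drop = FALSE])
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design))
    stop("covariate design is rank-deficient after dropping constants")
  resid <- qr.resid(qr_d, em$values)
  dimnames(resid) <- dimnames(em$values)
  expression_matrix(resid, state = to)
}

#' Read / write expression tables
#'
#' The on-disk format is TSV with a `gene_id` column followed by one column
#' per sample; the processing state is carried in a `#state=` header comment.
#'
#' @param em an [expression_matrix()].
#' @param path file path.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an [expression_matrix()].
#' @export
write_expression_tsv <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#state=%s", em$state), con)
  df <- data.frame(gene_id = em$gene_ids,
                   t(em$values), check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  first <- readLines(path, n = 1)
  state <- if (startsWith(first, "#state="))
    sub("^#state=", "", first) else "raw"
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  values <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(values) <- df$gene_id
  expression_matrix(values, state = state)
}
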