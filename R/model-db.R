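#' Persist a model set as a PrediXcan-compatible weight database
#'
#' Writes a single-file SQLite database with the two tables the PrediXcan
#' ecosystem expects: `weights` (`rsid`, `gene`, `weight`, `ref_allele`,
#' `eff_allele`) and `extra` (`gene`, `genename`, `pred.perf.R2`,
#' `pred.perf.pval`, `n.snps.in.model`). A third `construction` table
#' (key/value) records the stratum, sample count and fit parameters so that
#' [read_model_db()] round-trips the set.
#'
#' @param ms a `model_set` whose weights carry `effect_allele` /
#'   `other_allele` columns (as produced by [build_stratified_models()]).
#' @param path output path for the SQLite file.
#' @return `path`, invisibly.
#' @export
write_model_db <- function(ms, path) {
  stopifnot(inherits(ms, "model_set"))
  if (file.exists(path)) file.remove(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  weights <- do.call(rbind, lapply(ms$models, function(m) {
    w <- m$weights
    data.frame(rsid = w$variant_id, gene = m$gene_id, weight = w$weight,
               ref_allele = w$other_allele %||% rep(NA_character_, nrow(w)),
               eff_allele = w$effect_allele %||% rep(NA_character_, nrow(w)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(weights))
    weights <- data.frame(rsid = character(), gene = character(),
                          weight = numeric(), ref_allele = character(),
                          eff_allele = character())
  extra <- data.frame(
    gene = vapply(ms$models, `[[`, character(1), "gene_id"),
    genename = vapply(ms$models, `[[`, character(1), "gene_id"),
    `pred.perf.R2` = vapply(ms$models, `[[`, numeric(1), "cv_r2"),
    `pred.perf.pval` = vapply(ms$models, `[[`, numeric(1), "cv_pvalue"),
    `n.snps.in.model` = vapply(ms$models, function(m)
      as.integer(m$n_snps_in_model), integer(1)),
    check.names = FALSE, stringsAsFactors = FALSE, row.names = NULL)
  construction <- data.frame(
    key = c("stratum", "n_samples",
            paste0("alpha.", names(ms$models)),
            paste0("lambda.", names(ms$models)),
            paste0("n_snps_in_window.", names(ms$models)),
            paste0("seed.", names(ms$models))),
    value = c(ms$stratum, as.character(ms$n_samples),
              vapply(ms$models, function(m) as.character(m$alpha), character(1)),
              vapply(ms$models, function(m)
                formatC(m$lambda, format = "g", digits = 17), character(1)),
              vapply(ms$models, function(m)
                as.character(m$n_snps_in_window), character(1)),
              vapply(ms$models, function(m) as.character(m$seed), character(1))),
    stringsAsFactors = FALSE)
  DBI::dbWriteTable(con, "weights", weights)
  DBI::dbWriteTable(con, "extra", extra)
  DBI::dbWriteTable(con, "construction", construction)
  invisible(path)
}

#' Read a PrediXcan-compatible weight database
#'
#' @param path SQLite file with `weights` and `extra` tables (the format
#'   written by [write_model_db()]; databases from other tools work too —
#'   fields absent there, such as fit parameters, come back NA).
#' @return A `model_set`.
#' @export
read_model_db <- function(path) {
  if (!file.exists(path)) stop("model database not found: ", path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  tabs <- DBI::dbListTables(con)
  for (required in c("weights", "extra"))
    if (!required %in% tabs)
      stop(sprintf("model database %s is missing the '%s' table",
                   path, required))
  weights <- DBI::dbReadTable(con, "weights", check.names = FALSE)
  extra <- DBI::dbReadTable(con, "extra", check.names = FALSE)
  cons <- if ("construction" %in% tabs)
    DBI::dbReadTable(con, "construction") else
      data.frame(key = character(), value = character())
  lookup <- function(key, default = NA_character_) {
    hit <- cons$value[cons$key == key]
    if (length(hit)) hit[1] else default
  }
  stratum <- lookup("stratum", "all")
  n_samples <- suppressWarnings(as.integer(lookup("n_samples")))
  models <- lapply(seq_len(nrow(extra)), function(i) {
    gene <- extra$gene[i]
    w <- weights[weights$gene == gene, , drop = FALSE]
    structure(list(
      gene_id = gene, stratum = stratum,
      weights = data.frame(variant_id = w$rsid, weight = w$weight,
                           effect_allele = w$eff_allele,
                           other_allele = w$ref_allele,
                           stringsAsFactors = FALSE),
      n_snps_in_window = suppressWarnings(
        as.integer(lookup(paste0("n_snps_in_window.", gene)))),
      n_snps_in_model = as.integer(extra$`n.snps.in.model`[i]),
      cv_r2 = extra$`pred.perf.R2`[i],
      cv_pvalue = extra$`pred.perf.pval`[i],
      alpha = suppressWarnings(as.numeric(lookup(paste0("alpha.", gene)))),
      lambda = suppressWarnings(as.numeric(lookup(paste0("lambda.", gene)))),
      seed = suppressWarnings(as.integer(lookup(paste0("seed.", gene))))),
      class = "gene_model")
  })
  model_set(models, stratum = stratum, n_samples = n_samples)
}
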