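test_that("cis-SNP selection uses an inclusive window around the TSS", {
  variants <- data.frame(
    id = c("at_tss", "edge_lo", "edge_hi", "out_lo", "out_hi", "other_chr"),
    chrom = c(rep("1", 5), "2"),
    pos = c(5e6, 4e6, 6e6, 4e6 - 1, 6e6 + 1, 5e6))
  got <- select_cis_snps(5e6, variants, window_bp = 1e6, chrom = "1")
  expect_setequal(got, c("at_tss", "edge_lo", "edge_hi"))
  expect_error(select_cis_snps(5e6, variants, chrom = "99"),
               "unknown chromosome")
  expect_error(select_cis_snps(5e6, variants), "multiple chromosomes")
})

test_that("fixed-lambda elastic net matches the coordinate-descent oracle", {
  set.seed(42)
  for (rep in 1:5) {   # 20 instances run in the acceptance suite
    n <- sample(20:50, 1)
    p <- sample(2:10, 1)
    x <- matrix(rnorm(n * p), n)
    y <- drop(x %*% rnorm(p, 0, 0.5)) + rnorm(n)
    lambda <- runif(1, 0.01, 0.5)
    ours <- enet_coefficients(x, y, lambda, alpha = 0.5)
    oracle <- enet_cd_oracle(x, y, lambda, alpha = 0.5)
    expect_lt(max(abs(unname(ours) - oracle)), 1e-6)
  }
})

test_that("pure ridge with one standardized predictor matches the closed form", {
  set.seed(9)
  n <- 60
  x <- rnorm(n)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- 1.5 * x + rnorm(n)
  y <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))  # unit scale: objective exact
  for (lambda in c(0.05, 0.25, 1)) {
    b <- enet_coefficients(matrix(x), y, lambda, alpha = 0)[2]
    expect_equal(unname(b), sum(x * y) / (sum(x^2) + n * lambda),
                 tolerance = 1e-6)
  }
})

test_that("a noise-free single-SNP signal is recovered essentially perfectly", {
  set.seed(12)
  n <- 200
  d <- cbind(snpA = rbinom(n, 2, 0.3), snpB = rbinom(n, 2, 0.4),
             snpC = rbinom(n, 2, 0.2))
  rownames(d) <- paste0("s", 1:n)
  y <- 2 * d[, "snpA"]
  m <- fit_gene_model(d, y, gene_id = "g", seed = 5)
  expect_gt(m$cv_r2, 0.99)
  expect_lt(m$cv_pvalue, 1e-10)
  w <- setNames(m$weights$weight, m$weights$variant_id)
  expect_gt(w["snpA"], 1.5)
  expect_true(all(abs(w[setdiff(names(w), "snpA")]) < 0.1))
})

test_that("model fit statistics are invariant to sample order and affine response scaling", {
  set.seed(30)
  n <- 120
  d <- matrix(rbinom(n * 6, 2, 0.3), n, dimnames = list(paste0("s", 1:n)))
  colnames(d) <- paste0("v", 1:6)
  y <- setNames(0.8 * d[, 1] - 0.5 * d[, 3] + rnorm(n), rownames(d))
  base <- fit_gene_model(d, y, seed = 77)

  perm <- sample(n)
  reordered <- fit_gene_model(d[perm, ], y[perm], seed = 77)
  expect_equal(reordered$cv_r2, base$cv_r2, tolerance = 1e-12)
  expect_equal(reordered$weights, base$weights, tolerance = 1e-10)

  rescaled <- fit_gene_model(d, 3 * y + 10, seed = 77)
  expect_equal(rescaled$cv_r2, base$cv_r2, tolerance = 1e-8)
  expect_equal(rescaled$weights$weight, 3 * base$weights$weight,
               tolerance = 1e-6)
})

test_that("degenerate inputs are rejected or handled as no-model genes", {
  set.seed(2)
  d <- matrix(rbinom(60, 2, 0.3), 30, 2, dimnames = list(paste0("s", 1:30)))
  expect_error(fit_gene_model(d, rep(1, 30)), "zero variance")
  expect_error(fit_gene_model(d[1:10, ], rnorm(10)), "samples")

  # pure noise often selects no SNPs; such genes drop out of the model set
  ms <- model_set(list(fit_gene_model(d, rnorm(30), gene_id = "nullgene",
                                      n_outer_folds = 5, n_inner_folds = 5)))
  expect_true(length(ms$models) %in% c(0L, 1L))
  if (length(ms$models))
    expect_gt(ms$models$nullgene$n_snps_in_model, 0)
})

test_that("single-SNP genes fit without a second predictor", {
  set.seed(8)
  n <- 100
  d <- matrix(rbinom(n, 2, 0.4), n, 1,
              dimnames = list(paste0("s", 1:n), "only_snp"))
  y <- 1.2 * d[, 1] + rnorm(n, 0, 0.5)
  m <- fit_gene_model(d, y, seed = 3)
  expect_identical(m$n_snps_in_window, 1L)
  expect_identical(m$weights$variant_id, "only_snp")
  expect_equal(m$weights$weight, 1.2, tolerance = 0.25)
})

test_that("model filters apply strict thresholds", {
  mk <- function(r2, p) structure(
    list(gene_id = sprintf("g_%g_%g", r2, p), stratum = "all",
         weights = data.frame(variant_id = "v", weight = 1),
         n_snps_in_window = 1L, n_snps_in_model = 1L, cv_r2 = r2,
         cv_pvalue = p, alpha = 0.5, lambda = 0.1, seed = 1L),
    class = "gene_model")
  ms <- model_set(list(mk(0.01, 0.001), mk(0.5, 0.049), mk(0.5, 0.05),
                       mk(0.011, 0.01)))
  kept <- filter_models(ms)
  expect_setequal(names(kept$models), c("g_0.5_0.049", "g_0.011_0.01"))
  expect_length(filter_models(model_set(list()))$models, 0)
})

test_that("stratified builds recover the sex-specific architecture", {
  cfg <- simulation_config(n_train = 300, n_validate = 60, frac_female = 0.5,
                           n_genes = 4, cis_snps_per_gene = 8, n_causal = 2,
                           gene_class_mix = c(shared = 0.25, male_specific = 0.25,
                                              female_specific = 0.25, null = 0.25),
                           h2_male = 0.4, h2_female = 0.4, seed = 55)
  study <- simulate_cohorts(cfg)
  em <- residualize(
    inverse_normal_transform(
      expression_matrix(study$train$expression$values, "filtered")),
    study$train$covariates)
  sets <- build_stratified_models(study$train$genotypes, em,
                                  study$train$sex, study$genes,
                                  config = list(seed = 5))
  gt <- study$train$ground_truth
  male_gene <- gt$gene_id[gt$class == "male_specific"]
  null_gene <- gt$gene_id[gt$class == "null"]
  shared_gene <- gt$gene_id[gt$class == "shared"]

  expect_true(shared_gene %in% names(sets$all$models))
  expect_true(male_gene %in% names(sets$male$models))
  expect_false(male_gene %in% names(sets$female$models))
  expect_false(null_gene %in% names(sets$male$models) &&
                 null_gene %in% names(sets$female$models))
  # weights carry harmonization alleles
  w <- sets$all$models[[shared_gene]]$weights
  expect_true(all(c("effect_allele", "other_allele") %in% names(w)))
  # overlap partition sums to the number of distinct modeled genes
  ov <- summarize_study(sets)$overlap
  expect_identical(sum(ov[setdiff(names(ov), "total")]),
                   ov[["total"]])
})

test_that("model database round-trips and reports schema problems", {
  cfg <- tiny_config(seed = 61, n_genes = 3L)
  study <- simulate_cohorts(cfg)
  em <- inverse_normal_transform(
    expression_matrix(study$train$expression$values, "filtered"))
  sets <- build_stratified_models(study$train$genotypes, residualize(em),
                                  study$train$sex, study$genes,
                                  config = list(seed = 9, strata = "all"))
  ms <- sets$all
  skip_if(length(ms$models) < 1, "no gene modeled in tiny fixture")
  path <- tempfile(fileext = ".db")
  write_model_db(ms, path)
  back <- read_model_db(path)
  expect_identical(names(back$models), names(ms$models))
  expect_identical(back$stratum, ms$stratum)
  expect_identical(back$n_samples, ms$n_samples)
  for (g in names(ms$models)) {
    expect_equal(back$models[[g]]$weights, ms$models[[g]]$weights,
                 tolerance = 1e-12)
    expect_equal(back$models[[g]]$cv_r2, ms$models[[g]]$cv_r2)
    expect_equal(back$models[[g]]$lambda, ms$models[[g]]$lambda,
                 tolerance = 1e-12)
  }
  # weights table row count equals the sum of per-model SNP counts
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  n_rows <- DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM weights")$n
  DBI::dbDisconnect(con)
  expect_identical(n_rows,
                   sum(vapply(ms$models, `[[`, integer(1), "n_snps_in_model")))

  # a database without the `extra` table is rejected by name
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbRemoveTable(con, "extra")
  DBI::dbDisconnect(con)
  expect_error(read_model_db(path), "extra")
  expect_error(read_model_db(tempfile()), "not found")
})
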