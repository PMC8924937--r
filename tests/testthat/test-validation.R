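test_that("observed-on-predicted regression matches hand-computed OLS", {
  x <- c(0, 1, 2, 3, 4)
  y <- c(1, 1, 2, 2, 3)
  r <- regress_observed_on_predicted(y, x)
  expect_equal(r$beta, 0.5)            # Sxy / Sxx = 5 / 10
  expect_equal(r$r2, 25 / 28)          # Sxy^2 / (Sxx * Syy) = 25 / (10 * 2.8)
  expect_equal(r$pvalue, cor.test(x, y)$p.value)

  ident <- regress_observed_on_predicted(x, x)
  expect_equal(ident$beta, 1)
  expect_equal(ident$r2, 1)
  expect_lt(ident$pvalue, 1e-8)

  neg <- regress_observed_on_predicted(-x, x)
  expect_equal(neg$beta, -1)
  expect_equal(neg$r2, 1)              # r2 is sign-blind; beta carries sign

  expect_error(regress_observed_on_predicted(y, rep(1, 5)), "zero variance")
  expect_error(regress_observed_on_predicted(y[1:3], x[1:3]), ">= 4")
})

test_that("identical predictors give a degenerate zero-width bootstrap interval", {
  set.seed(1)
  y <- rnorm(30)
  x <- rnorm(30)
  ci <- bootstrap_delta_r2(y, x, x, n_boot = 200, seed = 3)
  expect_equal(ci$ci_low, 0)
  expect_equal(ci$ci_high, 0)
  expect_equal(ci$delta_r2, 0)
  expect_error(bootstrap_delta_r2(y[1:5], x[1:5], x[1:5]), ">= 10")
})

test_that("bootstrap interval is reproducible and centered sensibly", {
  set.seed(10)
  n <- 150
  z1 <- rnorm(n); z2 <- rnorm(n)
  y <- sqrt(0.2) * z1 + sqrt(0.08) * z2 + sqrt(0.72) * rnorm(n)
  sex_pred <- sqrt(0.2) * z1 + sqrt(0.08) * z2
  whole_pred <- z1
  a <- bootstrap_delta_r2(y, sex_pred, whole_pred, n_boot = 500, seed = 7)
  b <- bootstrap_delta_r2(y, sex_pred, whole_pred, n_boot = 500, seed = 7)
  expect_identical(a, b)
  expect_lt(a$ci_low, a$ci_high)
  # point estimate inside its own interval
  expect_gte(a$delta_r2, a$ci_low)
  expect_lte(a$delta_r2, a$ci_high)
  # lower bound above zero implies a positive point estimate
  if (a$ci_low > 0) expect_gt(a$delta_r2, 0)
})

test_that("gene classification covers every case exactly once", {
  rec <- function(beta, p, r2) list(beta = beta, pvalue = p, r2 = r2, n = 100)
  expect_identical(
    classify_gene(rec(0.8, 0.01, 0.30), rec(0.7, 0.01, 0.21))$category,
    "validated_sex_specific")
  expect_identical(
    classify_gene(rec(0.5, 0.2, 0.10), rec(0.9, 0.001, 0.25))$category,
    "validated_whole_sample")
  expect_identical(
    classify_gene(rec(0.5, 0.2, 0.10), rec(0.2, 0.4, 0.05))$category,
    "direction_consistent_only")
  expect_identical(
    classify_gene(rec(-0.5, 0.001, 0.30), rec(-0.2, 0.4, 0.05))$category,
    "not_validated")
  # exact R2 tie validates neither strict comparison
  tie <- classify_gene(rec(0.8, 0.01, 0.25), rec(0.8, 0.01, 0.25))
  expect_false(tie$category %in% c("validated_sex_specific",
                                   "validated_whole_sample"))

  # totality: every random record pair lands in exactly one category
  set.seed(2)
  cats <- replicate(200, {
    a <- rec(rnorm(1), runif(1), runif(1))
    b <- rec(rnorm(1), runif(1), runif(1))
    classify_gene(a, b)$category
  })
  expect_true(all(cats %in% c("validated_sex_specific",
                              "validated_whole_sample",
                              "direction_consistent_only", "not_validated")))

  # bootstrap interval drives the significance flag
  ci_pos <- list(ci_low = 0.02, ci_high = 0.1)
  ci_span <- list(ci_low = -0.01, ci_high = 0.1)
  expect_true(classify_gene(rec(1, 0.01, 0.3), rec(1, 0.01, 0.2),
                            ci_pos)$significant)
  expect_false(classify_gene(rec(1, 0.01, 0.3), rec(1, 0.01, 0.2),
                             ci_span)$significant)
})

test_that("study summary reproduces direct recomputation", {
  mk <- function(g, r2, stratum) structure(
    list(gene_id = g, stratum = stratum,
         weights = data.frame(variant_id = "v", weight = 1),
         n_snps_in_window = 1L, n_snps_in_model = 1L, cv_r2 = r2,
         cv_pvalue = 0.001, alpha = 0.5, lambda = 0.1, seed = 1L),
    class = "gene_model")
  sets <- list(
    all = model_set(list(mk("g1", 0.1, "all"), mk("g2", 0.3, "all")),
                    n_samples = 100L),
    male = model_set(list(mk("g1", 0.2, "male")), n_samples = 60L),
    female = model_set(list(), stratum = "female", n_samples = 40L))
  s <- summarize_study(sets)
  row_all <- s$model_performance[s$model_performance$stratum == "all", ]
  expect_equal(row_all$mean_r2, 0.2)
  expect_equal(row_all$se_r2, sd(c(0.1, 0.3)) / sqrt(2))  # 0.1
  expect_equal(row_all$se_r2, 0.1, tolerance = 1e-12)
  expect_equal(c(row_all$min_r2, row_all$max_r2), c(0.1, 0.3))
  expect_identical(s$model_performance$n_genes[
    s$model_performance$stratum == "female"], 0L)
  expect_identical(unname(s$overlap["all_male"]), 1L)
  expect_identical(unname(s$overlap["all_only"]), 1L)
  expect_identical(unname(s$overlap["total"]), 2L)

  records <- data.frame(
    gene_id = c("g1", "g2", "g3"), stratum = c("male", "male", "female"),
    beta = 1, pvalue = 0.01, r2_sex = c(0.5, 0.3, 0.2),
    r2_whole = c(0.2, 0.25, 0.1),
    delta_r2 = c(0.3, 0.05, 0.1), ci_low = NA, ci_high = NA, n_boot = 0L,
    validated = c(TRUE, FALSE, TRUE), significant = c(TRUE, NA, FALSE),
    category = "x")
  s2 <- summarize_study(sets, records)
  expect_equal(s2$delta_r2$male$mean, mean(c(0.3, 0.05)))
  expect_equal(s2$delta_r2$male$frac_gt_0.2, 0.5)
  v_male <- s2$validation[s2$validation$stratum == "male", ]
  expect_identical(v_male$n_validated, 1L)
  expect_identical(v_male$n_significant, 1L)
})

test_that("validate_predictions assembles per-gene records end to end", {
  set.seed(20)
  n <- 80
  ids <- paste0("s", 1:n)
  z <- rnorm(n)
  obs <- expression_matrix(
    matrix(c(z + rnorm(n, 0, 0.5), rnorm(n)), n, 2,
           dimnames = list(ids, c("signal", "noise"))), "residualized")
  mk_pred <- function(vals, stratum) structure(
    list(values = vals, stratum = stratum, sample_ids = ids,
         gene_ids = colnames(vals), coverage = NULL,
         zero_fraction = colMeans(abs(vals) < 1e-12),
         harmonization = NULL), class = "predicted_expression")
  pred_sex <- mk_pred(matrix(c(z, rnorm(n)), n, 2,
                             dimnames = list(ids, c("signal", "noise"))),
                      "male")
  pred_whole <- mk_pred(matrix(c(z + rnorm(n, 0, 2), rnorm(n)), n, 2,
                               dimnames = list(ids, c("signal", "noise"))),
                        "all")
  rec <- validate_predictions(obs, pred_sex, pred_whole, sex = "male",
                              n_boot = 200, seed = 8)
  expect_setequal(rec$gene_id, c("signal", "noise"))
  sig <- rec[rec$gene_id == "signal", ]
  expect_identical(sig$category, "validated_sex_specific")
  expect_true(sig$validated)
  expect_gt(sig$delta_r2, 0)
  expect_false(is.na(sig$ci_low))
  noi <- rec[rec$gene_id == "noise", ]
  expect_false(noi$validated)
  expect_identical(noi$n_boot, 0L)  # only validated genes bootstrapped
})
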