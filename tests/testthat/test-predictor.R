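test_that("allele harmonization distinguishes match, flip, ambiguity and mismatch", {
  expect_identical(harmonize_alleles("G", "A", "A", "G"), "match")
  expect_identical(harmonize_alleles("A", "G", "A", "G"), "flip")
  expect_identical(harmonize_alleles("A", "T", "A", "T"), "ambiguous_drop")
  expect_identical(harmonize_alleles("C", "G", "G", "C"), "ambiguous_drop")
  expect_identical(harmonize_alleles("A", "G", "A", "C"), "mismatch_drop")
})

mk_model_set <- function(weights_list, stratum = "all") {
  models <- lapply(names(weights_list), function(g) {
    w <- weights_list[[g]]
    structure(list(gene_id = g, stratum = stratum, weights = w,
                   n_snps_in_window = nrow(w),
                   n_snps_in_model = nrow(w), cv_r2 = 0.5, cv_pvalue = 1e-4,
                   alpha = 0.5, lambda = 0.1, seed = 1L),
              class = "gene_model")
  })
  model_set(models, stratum = stratum, n_samples = 10L)
}

test_that("prediction is the weighted dosage sum with flips and absences handled", {
  dos <- matrix(c(0, 1, 2), 3, 1, dimnames = list(paste0("s", 1:3), "v1"))
  gm <- toy_genotypes(dos, ref = "A", alt = "G")
  ms <- mk_model_set(list(
    g1 = data.frame(variant_id = "v1", weight = 0.5,
                    effect_allele = "G", other_allele = "A"),
    g2 = data.frame(variant_id = "v1", weight = 0.5,
                    effect_allele = "A", other_allele = "G"),
    g3 = data.frame(variant_id = "vX", weight = 1,
                    effect_allele = "G", other_allele = "A")))
  pred <- predict_expression(gm, ms)
  expect_equal(unname(pred$values[, "g1"]), c(0, 0.5, 1))
  # flip: weight * (2 - dosage)
  expect_equal(unname(pred$values[, "g2"]), 0.5 * (2 - c(0, 1, 2)))
  # absent SNP contributes zero, coverage 0
  expect_equal(unname(pred$values[, "g3"]), c(0, 0, 0))
  expect_equal(unname(pred$coverage), c(1, 1, 0))
  expect_equal(unname(pred$zero_fraction[c("g1", "g3")]), c(1 / 3, 1))
  expect_identical(
    pred$harmonization$decision[pred$harmonization$gene == "g3"], "absent")
  expect_error(predict_expression(gm, model_set(list())), "empty")
})

test_that("flipping the stored allele orientation only shifts predictions by a constant", {
  set.seed(6)
  dos <- matrix(rbinom(60, 2, 0.4), 20, 3)
  dimnames(dos) <- list(paste0("s", 1:20), c("a", "b", "c"))
  gm <- toy_genotypes(dos, ref = "A", alt = "G")
  w_match <- data.frame(variant_id = c("a", "b"), weight = c(0.7, -0.2),
                        effect_allele = "G", other_allele = "A")
  w_flip <- data.frame(variant_id = c("a", "b"), weight = -c(0.7, -0.2),
                       effect_allele = "A", other_allele = "G")
  p1 <- predict_expression(gm, mk_model_set(list(g = w_match)))$values[, "g"]
  p2 <- predict_expression(gm, mk_model_set(list(g = w_flip)))$values[, "g"]
  shift <- p2 - p1
  expect_equal(max(shift) - min(shift), 0, tolerance = 1e-12)
  expect_equal(unname(shift[1]), -2 * sum(w_match$weight), tolerance = 1e-12)
  expect_equal(cor(p1, p2), 1, tolerance = 1e-12)
})

test_that("prediction is linear in the weights", {
  set.seed(7)
  dos <- matrix(rbinom(100, 2, 0.3), 25, 4)
  dimnames(dos) <- list(paste0("s", 1:25), paste0("v", 1:4))
  gm <- toy_genotypes(dos, ref = "T", alt = "C")
  w <- data.frame(variant_id = paste0("v", 1:4), weight = rnorm(4),
                  effect_allele = "C", other_allele = "T")
  w3 <- transform(w, weight = 3 * weight)
  p1 <- predict_expression(gm, mk_model_set(list(g = w)))$values
  p3 <- predict_expression(gm, mk_model_set(list(g = w3)))$values
  expect_equal(p3, 3 * p1, tolerance = 1e-12)
})

test_that("strand-ambiguous model SNPs are dropped regardless of cohort alleles", {
  dos <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2,
                dimnames = list(paste0("s", 1:3), c("amb", "ok")))
  gm <- toy_genotypes(dos, ref = c("A", "A"), alt = c("T", "G"))
  w <- data.frame(variant_id = c("amb", "ok"), weight = c(5, 1),
                  effect_allele = c("T", "G"), other_allele = c("A", "A"))
  pred <- predict_expression(gm, mk_model_set(list(g = w)))
  expect_equal(unname(pred$values[, "g"]), c(2, 1, 0))  # only "ok" counts
  expect_equal(unname(pred$coverage), 0.5)
  expect_identical(
    pred$harmonization$decision[pred$harmonization$variant_id == "amb"],
    "ambiguous_drop")
})

test_that("the uninformativeness filter drops genes strictly above 90% zeros", {
  values <- cbind(mostly_zero = c(rep(0, 91), rnorm(9)),
                  at_boundary = c(rep(0, 90), rnorm(10)),
                  dense = rnorm(100))
  pred <- structure(list(
    values = values, stratum = "all",
    sample_ids = paste0("s", 1:100), gene_ids = colnames(values),
    coverage = setNames(rep(1, 3), colnames(values)),
    zero_fraction = colMeans(abs(values) < 1e-12),
    harmonization = NULL), class = "predicted_expression")
  kept <- filter_uninformative(pred)
  expect_setequal(colnames(kept$values), c("at_boundary", "dense"))
})

test_that("full-coverage prediction on the training cohort equals the design-matrix product", {
  cfg <- tiny_config(seed = 71, n_genes = 3L)
  study <- simulate_cohorts(cfg)
  em <- residualize(inverse_normal_transform(
    expression_matrix(study$train$expression$values, "filtered")),
    study$train$covariates)
  sets <- build_stratified_models(study$train$genotypes, em,
                                  study$train$sex, study$genes,
                                  config = list(seed = 4, strata = "all"))
  skip_if(length(sets$all$models) < 1, "no gene modeled in tiny fixture")
  pred <- predict_expression(study$train$genotypes, sets$all)
  for (g in names(sets$all$models)) {
    w <- sets$all$models[[g]]$weights
    manual <- drop(study$train$genotypes$dosages[, w$variant_id,
                                                 drop = FALSE] %*% w$weight)
    expect_equal(unname(pred$values[, g]), unname(manual), tolerance = 1e-12)
    expect_equal(unname(pred$coverage[g]), 1)
  }
})
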