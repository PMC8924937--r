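Package: sagex
Title: Sex-Aware Genetically Regulated Expression Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds sex-stratified and whole-sample cis-genetic models of gene
    expression by nested cross-validated elastic net, applies them to
    independent genotype cohorts, and decides per gene whether sex-specific
    models validate and outperform whole-sample models via within-sex
    regression and bootstrapped R-squared differences. Includes genotype and
    expression quality control mirroring standard TWAS pipelines, a
    PrediXcan-compatible weight database reader and writer, and a synthetic
    cohort generator with known shared and sex-specific cis-genetic
    architecture so every stage can be checked against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    vcfR,
    DBI,
    RSQLite,
    digest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
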