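Package: grsbmi
Title: Population-Standardized Genetic Risk Scores and BMI-by-Genetic-Risk
    Interaction Analysis for Prostate Biopsy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes a population-standardized multiplicative genetic risk
    score (GRS) from SNP panels with externally derived allelic odds ratios
    and risk-allele frequencies, stratifies subjects into GRS tertiles, and
    estimates stratum-specific body-mass-index (BMI) odds ratios and
    BMI-by-GRS-stratum interaction effects on prostate biopsy outcome with
    unconditional multiple logistic regression. Includes readers for SNP
    panel, genotype, and phenotype tables (CSV and VCF), a synthetic cohort
    generator with Hardy-Weinberg genotypes and a configurable
    stratum-specific logistic outcome model, baseline comparison tables
    (Kruskal-Wallis and chi-squared), and an end-to-end reproducible
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
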