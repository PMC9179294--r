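Package: mammotwin
Title: Twin and Sister Family Analysis of Mammographic Density Risk
    Scores and Breast Cancer Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the genetic basis of mammographic density
    in twin and sister family designs.  Simulates pedigreed cohorts
    (monozygotic and dizygotic twin pairs and non-twin sisters) with
    Mendelian genotype sharing and additive-polygenic density traits;
    derives mammogram risk scores (standardized residuals of Box-Cox
    transformed density measures after adjustment for age and inverse
    body mass index); computes polygenic risk scores from effect-allele
    dosages with genotype quality control (call rate, Hardy-Weinberg
    exact test, minor allele frequency, heterozygosity outliers); fits
    variance-components linear mixed models with family and zygosity
    random intercepts by restricted maximum likelihood; and drives the
    downstream association analyses (family-aware correlations with
    clustered bootstrap intervals, per-adjusted-standard-deviation
    scaled coefficients, Bayesian Information Criterion model
    comparison, mutual-adjustment attenuation, and per-SNP association
    screens with Bonferroni and excess-significance summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    MASS,
    optparse,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
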