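Package: dcmodel
Title: Dextral-Chance Genetic Models of Human Handedness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact algebra and Monte Carlo simulation for the dextral-chance
    (DC) genetic model of human handedness in single-locus and multilocus
    form. Provides Hardy-Weinberg genotype distributions, penetrance-based
    predictions for families, monozygotic and dizygotic twins, and
    hand-language pleiotropy; a damage-rule multilocus model with a
    closed-form prevalence equation and allele-frequency solver; a seedable
    pedigree simulator for nuclear families and twin pairs; and GWAS power
    and sample-size machinery for penetrance-based genetic models, including
    an allelic chi-square Monte Carlo power estimator at genome-wide
    significance.
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
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
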