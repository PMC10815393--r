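Package: cftrmonitor
Title: Indirect Allele-Frequency Estimation and Regional Comparison of CFTR Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates population allele frequencies of pathogenic CFTR
    variants indirectly from a cystic-fibrosis patient registry: disease
    prevalence from registry case counts over a birth-cohort horizon, the
    disease-allele frequency under Hardy-Weinberg equilibrium, and
    per-variant frequencies via the variant spectrum observed among
    patients. Compares indirect estimates with directly measured cohort
    frequencies using exact binomial confidence intervals and chi-squared
    contingency tests with a configurable Yates policy, and includes a
    synthetic-cohort generator with known ground truth for
    parameter-recovery validation of the whole estimation chain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
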