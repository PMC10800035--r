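Package: hetoa
Title: Genome-Wide Heterozygosity and Osteoarthritis Case-Control Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-individual genome-wide heterozygosity statistics
    (observed and expected heterozygosity, HetRate, HetExcess) from
    case-control genotype data, applies standard variant- and sample-level
    quality control (minor allele frequency, missingness, Hardy-Weinberg
    exact test, duplicate and sex-discordance checks), and fits logistic
    regression models of disease status on z-scored heterozygosity with
    covariate adjustment, reporting per-standard-deviation odds ratios.
    Includes a seeded synthetic-cohort generator in which per-individual
    inbreeding drives heterozygosity and disease risk, with injectable
    quality-control violations and recorded ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
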