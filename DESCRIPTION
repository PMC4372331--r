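Package: dmgscan
Title: Differential Mutation Analysis of Case-Control Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies differentially mutated genes and variants between
    two-class tumour cohorts from SIFT-annotated single-nucleotide variant
    tables. Computes an isoform-normalised per-gene, per-sample deleterious
    mutation burden score, tests genes for differential burden between
    clinical classes (two-sample t-test with Benjamini-Hochberg false
    discovery rates and fold changes), and contrasts individual variants by
    carrier odds ratios with two-sided Fisher exact tests, optionally
    restricted to protein-domain regions. Includes a seeded synthetic cohort
    generator with planted effects for power and calibration studies, a
    protein-stability consensus voter, and an end-to-end pipeline driver
    with a YAML configuration and JSON run manifest.
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
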