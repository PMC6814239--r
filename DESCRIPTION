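Package: acmgscore
Title: ACMG Criteria Assignment and Bayesian Pathogenicity Scoring for
    Annotated Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assigns the automatically derivable ACMG/AMP evidence criteria
    to ANNOVAR- or VEP-annotated exome variants, converts the categorical
    criteria into a continuous posterior probability of pathogenicity with
    a Bayesian points framework, detects cohort-enriched variants against
    public allele frequencies without control samples (PS4), flags de novo
    variants in parent-offspring trios (PS2), and produces filtered,
    by-sample and gene-burden cohort reports. Includes a synthetic cohort
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    httr,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
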