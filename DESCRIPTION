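Package: mmclonetrack
Title: Clonal Evolution Tracking in Longitudinal Multiple Myeloma Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired-sample targeted-panel sequencing of
    multiple myeloma. Implements a consensus somatic-variant filter cascade
    (population allele frequency, read support, pathogenicity-predictor
    consensus with a recurrent-gene exception, ACMG-class rejection with a
    whitelist), paired-sample variant-allele-frequency trajectory
    classification and patient-level evolution patterns, prognostic
    copy-number event calling from segment log2 ratios including biallelic
    and double/triple-hit detection, dynamic ISS and R-ISS restaging, and
    survival analysis of the resulting risk groups. A synthetic-cohort
    simulator with ground-truth labels makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    rlang,
    jsonlite,
    survival,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
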