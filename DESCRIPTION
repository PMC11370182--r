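Package: dqpheno
Title: Data-Quality Robustness Analysis for Computable EHR Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how rule-based (computable) phenotype
    definitions degrade under controlled electronic-health-record data-quality
    defects. Provides a tabular EHR cohort model (demographics plus diagnosis,
    medication and laboratory event streams), a calibrated synthetic cohort
    generator, a declarative phenotype language with five shipped type-2-
    diabetes definitions (CCW, DDC, SUPREME-DM, eMERGE, JHU), seeded and
    nestable perturbation operators for incompleteness, inaccuracy and
    timeliness, and experiment runners producing retention curves, data-type
    strata, Charlson comorbidity summaries and 31-region overlap partitions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    yaml,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
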