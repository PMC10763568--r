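Package: ssmc11
Title: Dosage-Sensitivity Mapping of the Pericentric Region of Human
    Chromosome 11 from sSMC Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to curate cohorts of small supernumerary marker
    chromosome (sSMC) carriers and sSMC-like duplication cases, parse the
    ISCN-style karyotype nomenclature used in such case tables, resolve
    cytoband, FISH-probe and array evidence into per-case trisomic
    intervals on GRCh37, and infer the minimal pericentric
    triplo-insensitive span of chromosome 11 together with bounded
    uncertainty windows for the start of triplo-sensitive territory on
    each arm. Includes cohort descriptive statistics, an arm-wise
    genotype-phenotype tabulation, and a synthetic-cohort simulator with
    known ground truth for validating the inference.
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
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
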