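Package: coipquant
Title: Spectral-Count Quantification for Cellulose Synthase Complex
    Co-Immunoprecipitation Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free quantification and classification of
    co-immunoprecipitation LC-MS/MS spectral counts for cellulose and
    callose synthase complex proteomics in cotton fiber. Computes
    cellulase-treatment enhancement percentages from total and distinct
    peptide counts across replicated experiments, classifies proteins into
    treatment-enhanced and non-enhanced groups, filters candidate
    interactors against pre-immune serum controls by fold enrichment,
    converts radiolabel incorporation (cpm) to nmol of glucose in the in
    vitro glucan synthesis assay, and groups candidate genes by Spearman
    rank co-expression across tissue compendia with hierarchical
    clustering. Includes seeded synthetic-data generators with planted
    ground truth for validating every classification stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
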