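Package: taxoutlier
Title: Per-Sample Detection of Overrepresented Microbial Taxa in Tissue Metatranscriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying microbial taxa overrepresented in individual
    case specimens relative to a control cohort in deep RNA sequencing of
    tissue. Converts filtered paired-end alignments against a panmicrobial
    reference catalog into concordant-pair counts, aggregates counts over a
    taxonomic hierarchy, normalizes to pairs-per-million hit rates, excludes
    run-specific contaminant taxa using blank (no-tissue) specimens, scores
    every case sample against the control distribution with per-taxon Z-scores
    and one-tailed normal p-values under Benjamini-Hochberg false discovery
    rate control, and summarizes, clusters and compares the resulting
    candidate taxa. Includes a ground-truthed synthetic data generator
    (negative-binomial counts with log-scale spike-ins, run-restricted
    contaminants, and SAM emission) so the full pipeline can be exercised
    end-to-end at desk scale.
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
    Rsamtools,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
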