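Package: oncoboard
Title: Somatic Variant Interpretation and Clinical Reporting for Molecular Tumor Boards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An interpretation engine for molecular tumor boards: merges
    per-caller somatic variant calls with a minimum-caller consensus rule,
    derives gene-level copy-number calls from segment data, compares tumor
    gene expression to a reference cohort, computes the tumor mutational
    burden, matches aberrations against a local drug-gene knowledge-base
    snapshot to produce tiered (A-D) therapy recommendations, resistance
    warnings and ranked clinical-trial options, and assembles structured
    level-1/level-2 clinical reports plus cohort-level summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
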