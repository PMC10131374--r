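Package: clonarch
Title: Clonality Estimation of Somatic Variants in ctDNA and Tissue with
    Co-Alteration and Outcome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates tumor (ctDNA) fraction from liquid-biopsy variant
    calls via the maximum somatic allele fraction (MSAF) or from tissue
    calls via per-variant copy-number-aware tumor fractions, computes
    per-variant clonal fractions, and classifies samples by the
    multiplicity and clonality of mutations in a target gene (PIK3CA by
    default).  Companion tools compare gene- and pathway-level
    co-alteration rates between clonality groups with exact contingency
    tests, summarise objective response rates with exact binomial
    confidence intervals, compare progression-free survival with
    Kaplan-Meier, log-rank and Cox models, and generate truth-labelled
    synthetic cohorts so every stage of the pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    vcfR,
    optparse
Config/testthat/edition: 3
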