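Package: qtap
Title: Quantitative Targeted Absolute Proteomics Workflows for MRM Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative targeted absolute proteomics (QTAP) by
    stable-isotope-dilution multiple reaction monitoring (MRM). Turns paired
    light/heavy transition peak areas into absolute protein expression
    (fmol per microgram total protein) with transition averaging,
    under-limit-of-quantification (ULQ) rules and dilution-series LLOQ
    determination; provides the accompanying statistical layer (pooled
    two-sample t-tests in raw and summary-statistic form, a robust
    FDR-controlled outlier screen, exact noncentral-t power and sample-size
    calculations), publication-shaped group-comparison tables with ULQ/NQ
    sentinels, cross-model fold-change classification, isotope-dilution
    relative quantification of amino acids, and efficiency-corrected
    delta-delta-Ct qPCR fold expression. A synthetic-data module generates
    transition-level MRM, amino-acid and Ct datasets with known ground truth
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
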