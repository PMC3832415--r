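Package: ripchip
Title: Enrichment Screening for Protein-Bound Small RNAs from RIP-Chip Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for RNA-immunoprecipitation microarray (RIP-chip)
    experiments that catalogue small noncoding RNAs bound by an RNA-binding
    protein. Implements robust multi-array average (RMA) normalisation
    (exponential-normal convolution background correction, quantile
    normalisation, median-polish probeset summarisation), spike-in based
    detection calls, IP:input enrichment screening with top-quantile
    selection, cross-cell-line overlap classification, empirical-Bayes
    moderated-t ranking of knockdown contrasts, and delta-delta-Ct relative
    quantification for qPCR validation. A synthetic-data generator emulating
    an Affymetrix miRNA 2.0 style platform design makes every stage testable
    without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
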