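Package: polytrans
Title: Polytranscriptomic Scoring and Post-TWAS Integration for Complex Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating transcriptome- and proteome-wide association
    study (TWAS/PWAS) summary statistics with fine-mapping, drug-gene
    interaction and observed case-control expression data. Implements
    high-confidence gene calling from colocalisation and HEIDI evidence,
    clumping of TWAS associations on a predicted-expression correlation
    matrix, polytranscriptomic score (PTS) calculation with p-value
    thresholding, liability-scale variance conversion, inverse-variance
    meta-analysis, directional drug-repurposing enrichment with ATC
    pharmacological-class testing, and concordance classification of
    predicted versus observed differential expression. A synthetic-data
    module generates every pipeline input with known ground truth so the
    full analysis can be exercised end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
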