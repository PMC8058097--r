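Package: oncoage
Title: Age-Association Analysis of Tumour Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying age-associated somatic alterations in
    tumour cohorts. Computes genome-instability scores, percent genomic
    loss of heterozygosity, ploidy and whole-genome-duplication calls from
    allele-specific copy-number segments; hierarchical (focal, arm,
    chromosome) somatic copy-number-alteration scores from GISTIC-style
    event tables with within-cohort rank normalisation; mutation burden,
    substitution-class fractions and hypermutation statistics from MAF
    tables; a screen-then-adjust regression cascade with Benjamini-Hochberg
    correction and Firth-penalized logistic regression as a separation
    fallback; coupled expression/methylation age regressions with
    probe-to-gene mapping and quadrant classification; and a synthetic
    cohort generator with planted, recoverable age effects for end-to-end
    validation without access to controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
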