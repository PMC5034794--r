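Package: sexcheck
Title: Detection of Sex-Misannotated Samples in Transcriptomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Audits transcriptomics datasets for sample mislabeling by
    comparing annotated sex against a gene-expression-based sex inferred
    from the sex-specific markers XIST (female-specific) and KDM5D and
    RPS4Y1 (male-specific). Provides readers for tab-separated and GEO
    series-matrix expression tables, log2/quantile-normalization
    preprocessing, correlation-based quality filtering of marker
    probesets, two-cluster k-means sex assignment with a
    median-difference ambiguity check, per-dataset and corpus-level
    mismatch reports, cross-study concordance analysis to separate
    physical sample mix-ups from metadata recording errors, one-sided
    binomial confidence bounds for the population prevalence of affected
    studies, and a synthetic-data generator that plants known label
    swaps for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
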