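Package: genomechanics
Title: Single-Cell Genomechanics: AFM Viscoelastic Curve Fitting and Gene
    Network Regulator Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to link single-cell mechanical phenotypes to gene
    expression. Extracts the apparent Young's modulus from the approach
    segment of atomic force microscopy (AFM) force curves via Hertzian
    sphere-on-half-space contact mechanics with automatic contact-point
    detection and refinement, and the fast and slow viscous rate constants
    from the dwell segment via a standard-linear-solid biexponential
    relaxation fit. Quantifies qPCR perturbation experiments by the
    delta-delta-Ct method with housekeeping-gene normalization and
    first-order error propagation, screens gene-by-mechanics Spearman rank
    correlations with exact small-sample p-values, and scores candidate
    upstream regulators of mechanically correlated gene sets by
    hypergeometric overlap, activation z-score, and a permutation-based
    hub-bias-corrected p-value. A full synthetic-data module generates
    force curves, coupled expression/mechanics matrices, Ct replicate
    tables, and signed hub-skewed regulatory networks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
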