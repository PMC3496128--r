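Package: pdxconcord
Title: Concordance Analysis of Patient Tumors and Derived Xenografts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing molecular profiles of patient tumors with
    their derived xenografts. Implements clone-level copy-number (gain/
    normal/loss) concordance on altered clones, group-average hierarchical
    clustering with pair co-segregation counting, construction of maximal
    constant-status chromosomal segments and detection of recurrent
    xenograft-specific copy-number differences, paired regression-residual
    differential expression with cross-pair recurrence and a direction
    trend test, nearest-centroid molecular subtype classification with an
    unclassified threshold, and hypergeometric gene-set over-representation
    with Benjamini-Hochberg correction. Includes simulators for paired
    copy-number and expression cohorts with known ground truth so every
    stage can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
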