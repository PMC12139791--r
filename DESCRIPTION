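Package: cpmshift
Title: Paired-Condition Shifts in Connectome-Based Network Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how a within-subject pharmacological
    manipulation shifts connectome-based network signatures. Computes Fisher
    z-transformed functional connectomes from parcellated node time series,
    applies run-level motion quality control, scores connectomes against
    binary edge masks (connectome-based predictive modeling network strength),
    performs paired condition inference including a Bonferroni-corrected
    canonical-network grid contrast, classifies conditions with a paired
    leave-one-subject-out linear support vector machine with a permutation
    null and edge-weight selection, tests edge-set overlap with hypergeometric
    tail probabilities, and scores go/no-go sustained-attention performance
    (d-prime). A synthetic-data generator plants condition effects on
    designated edges so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    e1071,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
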