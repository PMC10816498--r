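Package: xplexnorm
Title: Reference-Based Normalization and Paired Differential Analysis of
    Multiplex Bead-Immunoassay Cytokine Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares systemic (blood plasma) and local (tissue-explant
    conditioned medium) cytokine levels measured with multiplex bead
    immunoassays (xMAP/Luminex). Implements censoring-aware handling of
    concentrations outside the detection range (substitution imputation and
    interval construction), data-driven selection of reference cytokines by
    GeNorm-style pairwise-variation stability with a differential-representation
    screen, geometric-mean normalization factors, a two-branch paired
    differential analysis (Wilcoxon signed-rank for well-detected analytes, an
    interval-based exact sign test for heavily censored ones) with
    Benjamini-Hochberg false-discovery-rate control, Ward clustering to flag
    possible co-regulation of reference analytes, and delta-Ct relative qPCR
    quantification for verification. A synthetic-data generator with known
    ground truth makes every stage testable without external data.
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
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    optparse
Config/testthat/edition: 3
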