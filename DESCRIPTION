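Package: qzipper
Title: Q-Zipper Sequence Grammar and Single-Cell DAmFRET Analytics for
    Polyglutamine Amyloid Nucleation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how polyglutamine (polyQ) sequences nucleate
    amyloid. Implements a sequence grammar for the glutamine steric zipper
    (unilateral and bilateral contiguity, intramolecular threading of a
    four-stranded nucleus, de novo and template competence, minimal-nucleus
    design), a stochastic model of amyloid nucleation under rising
    intracellular concentration with optional self-poisoning that generates
    realistic synthetic flow-cytometry event tables, and the DAmFRET
    quantification pipeline (logicle transform, sequential scatter and
    expression gates, negative-control gate profiles, the fgate statistic,
    fraction-positive curves, intermediate-population and poisoning-plateau
    statistics). Also provides the accompanying microscopy quantification
    (sum projection, coefficient-of-variation puncta calls, ellipsoid cell
    volumes and concentrations) and SDD-AGE lane densitometry (rolling-ball
    background subtraction, lane profiles, integral normalization).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    Biostrings,
    mgcv,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
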