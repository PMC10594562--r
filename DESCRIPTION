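Package: thermoshift
Title: Thermal Proteome Profiling and Single-Tube Ramp (STPP-UP) Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of thermal shift proteomics experiments that quantify
    drug-induced protein stabilization from TMT reporter intensities. Covers
    the single-tube uniform-progression (STPP-UP) readout, in which one sample
    is heated along a continuous temperature ramp so stability differences
    accumulate into abundance differences, and the 2D-TPP readout based on
    per-temperature fold changes summarized into abundance and stability
    scores. Provides a two-state Arrhenius denaturation model with heating
    program survival integration and melting-curve fitting, a ground-truthed
    reporter-intensity simulator, MaxQuant proteinGroups-style input/output
    with the standard QC filter cascade, a generalized-log variance
    stabilizing normalization, empirical-Bayes moderated differential testing,
    score-based tail-area false discovery rates, and hit classification at the
    published thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    limma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
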