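Package: plasmapanel
Title: Discovery of Placenta-Derived Cell-Free RNA Markers in Maternal Plasma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for identifying
    pregnancy-complication-associated placental transcripts that are
    detectable in maternal plasma. Implements two-group microarray
    differential expression with an exact Mann-Whitney rank-sum test,
    Benjamini-Hochberg adjustment and a spike-in-calibrated fold-change
    threshold; selection of a plasma-candidate marker panel as the
    intersection of aberrantly expressed and highly expressed probesets
    anchored to a reference transcript; gene-ontology over-representation
    with fold of enrichment and the EASE-style modified Fisher exact test;
    MIQE-style RT-qPCR absolute quantification with calibration curves,
    amplification efficiency and an empirical 95-percent-detection limit of
    detection; and cohort-level inference on plasma detection rates (exact
    Fisher test, rate ratios, Kruskal-Wallis with Student-Newman-Keuls post
    hoc). A seeded synthetic-data generator emulates the study design so
    every stage can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
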