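Package: ecia
Title: Hit Calling for Reciprocal Extracellular Interaction Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for all-by-all extracellular interaction
    assay (ECIA) screens in which every protein pair is measured in both
    bait-prey and prey-bait orientations on protein-A plates and read out
    as absorbance at 650 nm. Normalizes the bait x prey absorbance matrix
    by Tukey two-way median polish to remove assay-wide and
    per-preparation background, scores residuals in screen-wide MAD
    units, calls unidirectional and bidirectional (geometric-mean)
    interactions at a fixed cutoff, and confirms hits against an
    independent retest screen via interquartile-range normalization, a
    data-derived confirmation threshold, and Spearman reproducibility.
    Includes a synthetic screen simulator with planted interactions and
    control wells so every stage of the pipeline can be validated
    against ground truth.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
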