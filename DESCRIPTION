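Package: asymhist
Title: Quantification of Asymmetric Histone Inheritance in Stem Cell Divisions
Version: 0.1.0
Authors@R:
    person("Midgut", "Imaging Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for quantifying dual-colour (old versus new)
    histone inheritance in intestinal stem cell divisions from multi-channel
    confocal z-stacks: Pearson/Spearman colocalization over regions of
    interest, background-corrected integrated-density measurement,
    sister-chromatid segregation ratios with control-derived asymmetry
    thresholds, postmitotic-pair Delta classification with log2 inheritance
    ratios and quadrant assignment, tissue-level cluster/census/profile
    statistics, and the accompanying statistical decision tree.  A seeded
    synthetic-microscopy generator plants ground truth for every measured
    configuration so the full pipeline is testable without raw image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
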