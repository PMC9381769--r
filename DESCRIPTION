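Package: hippotools
Title: Spatial Coding, Synaptic Densitometry and Home-Cage Learning Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studies of deep entorhinal
    (layer-6b/subplate) projections to the hippocampus. Implements
    occupancy-normalized place-cell rate maps with speed filtering and
    Gaussian smoothing, Skaggs spatial information (whole-map and
    per-quadrant) with session comparisons under quadrant-confined
    optogenetic inhibition, two-channel super-resolution punctum
    colocalization densitometry with area filtering, EPSC kinetic
    measurement (amplitude, onset latency, 20-80% rise time, decay time
    constant, half-width, paired-pulse ratio), and home-cage operant
    spatial-learning error-rate analysis with rank correlations. A
    synthetic-data module generates every input with known ground truth
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
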