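Package: myomorph
Title: Quantitative Morphometry of Remodelling Muscles in Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify muscle fibre remodelling during Drosophila
    metamorphosis from two-channel time-lapse fluorescence projections.
    Implements medial-axis morphometry (area, length, average chord diameter)
    of annotated muscle regions, head-eversion-aligned time-series analysis
    with per-timepoint medians and Mann-Whitney U group comparisons,
    myonuclear-distribution metrics (uniform basal, central cluster, midline
    row, scattered), and a seeded synthetic two-channel time-lapse generator
    with exact ground truth and genotype phenotype presets, so the full
    pipeline can be exercised and validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    jsonlite,
    yaml,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
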