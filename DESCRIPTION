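Package: barrelsync
Title: Stimulus-Frequency Response, Synchrony and Functional Connectivity
    for Two-Photon Calcium Imaging of Barrel Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for populations of barrel-cortex neurons and
    astrocytes imaged with a calcium indicator during paired whisker
    burst stimuli of increasing pulse frequency. Converts raw region-of-interest
    fluorescence (or small two-channel image stacks) into cleaned dF/F traces,
    detects active cells, measures paired burst responses (R1, R2) and
    classifies each cell as increment, decrement or parallel, quantifies
    pairwise synchrony by the peak of the lag-resolved Pearson
    cross-correlation, and converts correlation matrices into binary
    functional-connectivity graphs by thresholding at the spontaneous-activity
    mean + 2 SD, with the derived network percentages Pn, Pk and Pl. Includes
    an analytically calibrated synthetic-data generator (calcium traces,
    two-channel image stacks, local field potential sweeps) so that every
    stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
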