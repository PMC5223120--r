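Package: antArena
Title: Semi-Automated Monitoring of Seed Dispersal by Ants from Stitched Time-Lapse Imagery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying myrmecochory (seed dispersal by ants) in
    laboratory arenas from time-lapse imagery. Two overlapping camera views are
    luminosity-compensated and stitched along a hard stitch line (no blending)
    using an estimated homography; millimetre-scale seeds are detected with a
    modal-RGB background model, difference and darkness segmentation, a
    two-of-three temporal persistence filter, and size-gated blob
    classification that discriminates static seeds from moving ants. Seed
    occupancy episodes are tracked over time to quantify rejection dynamics and
    redispersal distances. Spatial statistics (nearest-neighbour G-function,
    Monte-Carlo CSR envelopes, the Diggle-Cressie-Loosmore-Ford test,
    characteristic clustering distances, circular uniformity tests, radial
    density profiles) characterize rejected-seed patterns, and an agent-based
    simulator contrasts blind versus reactive centrifugal seed dropping. A
    synthetic-scene generator renders ground-truthed arena imagery so every
    pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    grDevices,
    data.table,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    tiff,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
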