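Package: zfhunt
Title: Tracking and Analysis of Larval Zebrafish Hunting Behavior and
    Isthmic Calcium Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for the analysis of larval zebrafish hunting
    behavior and associated neural activity. Provides video-based tracking of
    a freely swimming larva and its prey (background modelling, moments-based
    body and eye pose, annular tail tracing, Gaussian prey detection and
    Hungarian track linking), kinematic segmentation of hunting routines from
    ocular vergence, per-bout pursuit gain metrics and outcome ethograms,
    loom-contrast psychometric fits, and trial-based calcium-trace statistics
    (visual response vector clustering and the convergence modulation index
    with a circular-shuffle null). A synthetic-data generator produces
    ground-truthed behavioral sessions, rendered video frames and
    trial-structured calcium recordings against which every stage of the
    pipeline is validated.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    mclust,
    tiff,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
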