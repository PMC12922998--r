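Package: colormotion
Title: Color-from-Motion Video Encoding, Dataset Compilation and Multi-Object Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying animal behavior from video using a
    color-from-motion representation: inter-frame luminance differences are
    smoothed over several timescales and mapped into the blue, green and red
    channels, so that the color of a motion trail encodes time-since-motion
    and its geometry encodes speed, acceleration and direction. The package
    provides the encoder (exponential and sequential strategies, chromatic
    tails, luminance blending, frame skipping), a synthetic-scene generator
    with per-frame ground truth, compilation of dual-stream (static/motion)
    annotation datasets in YOLO darknet layout with probabilistic train/val
    splitting, gray-box shielding and auto-annotation, duplicate-detection
    merging across streams, Kalman-filter multi-object tracking with stable
    identities, hierarchical primary/secondary class dispatch, and a batch
    processing pipeline with CSV output. Detection itself is delegated to a
    pluggable detector interface; a ground-truth oracle detector is included
    for testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    yaml,
    jsonlite,
    digest,
    clue,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
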