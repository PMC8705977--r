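Package: shuffledet
Title: Lightweight Shuffle-Block Detection of Animal Postures in Pen Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lightweight anchor-based object detector for monitoring the
    postures of group-housed animals (standing, lying on belly, lying on
    side, sitting, mounting) in top-view pen imagery. The backbone stacks
    symmetric compression blocks built from channel split/shuffle and 5x5
    depthwise separable convolutions, with efficient channel attention (ECA)
    after each stage; features are fused by a path-aggregation neck and
    decoded by anchor-based YOLO heads with non-maximum suppression. The
    package ships its own small convolution engine with exact
    backpropagation (vectorised on BLAS matrix products), an SGD training
    loop with genetic-algorithm hyperparameter evolution, COCO and LabelMe
    annotation I/O, precision/recall/AP/mAP and ROC evaluation, an analytic
    parameter and FLOP profiler, a seeded synthetic pen-scene generator for
    end-to-end testing, and 24-hour posture-proportion time series
    aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    png,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
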