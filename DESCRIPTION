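Package: pickpoint
Title: Picking-Point Localization for Terminal Flowers from Segmentation Masks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts corolla and stem instance segmentation masks of terminal
    flowers (such as marigold) into per-flower picking-point coordinates for
    harvesting robotics. Implements constrained ellipse fitting of the corolla
    with a fixed picking inclination and minor-axis safety scaling, Zhang-Suen
    skeletonization of the stem with branch pruning, and intersection-based
    point selection with a 90-degree fallback rotation. Includes the
    accuracy/wrong-point evaluation metrics with greedy point matching, a
    seeded synthetic scene generator with ground-truth calyx points, and an
    analytic parameter/FLOP audit of the lightweight segmentation
    architecture family the pipeline is designed around (StarNet backbone,
    Star-block feature-fusion neck, shared group-normalized segmentation
    head) against its YOLOv8n-seg baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
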