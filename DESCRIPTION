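Package: cfuhybrid
Title: Hybrid Colony-Forming Unit Counting from Petri Dish Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for counting colony-forming units (CFUs) on agar plates
    from photographs. Implements a multi-loss U-Net segmentation objective
    with an auxiliary bottleneck alignment term that steers the coarsest
    encoder features toward CFU centroids, a circle-Hough Petri dish
    localization cascade that recovers the dish, glass and water edges and
    the reflection-prone bezel annulus between them, and a hybrid counting
    rule that halves counts inside the bezel to correct for mirrored colony
    reflections. Ships a deterministic synthetic dish-scene generator with
    known ground truth so the whole pipeline (targets, losses, training,
    localization, post-processing, counting, evaluation) is testable end to
    end without external imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    grDevices,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
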