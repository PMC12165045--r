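Package: contourweight
Title: Contour-Based Instance Segmentation and Liveweight Estimation for
    Top-View Livestock Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A dual-network framework for non-contact liveweight estimation
    of group-housed animals from overhead RGB images. A contour information
    extraction network (CIEN) regresses and iteratively refines per-animal
    boundary polygons using multi-head self-attention over per-vertex image
    features, supervised by a debiased Sinkhorn optimal-transport divergence
    between predicted and ground-truth contour point sets; a lightweight
    liveweight estimation network (LWEN) regresses body weight in kilograms
    directly from normalized contour coordinates. Includes perceptual-hash
    frame deduplication, greedy multi-start TSP contour ordering, COCO-style
    mask average precision, a Kuhn-Munkres hard-assignment baseline, and a
    deterministic synthetic top-view scene generator with geometry-linked
    weights so the whole pipeline is testable offline on a CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
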