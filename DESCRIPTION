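Package: wingseg
Title: Weakly-Supervised Ingredient Segmentation from Classification Feature Maps
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for segmenting food ingredients in multi-ingredient images
    without pixel-level training labels. A gated convolutional network is
    trained as a single-ingredient classifier on image-level labels organised
    in a four-level ingredient taxonomy (optionally with a weighted multi-level
    loss across all taxonomy levels). The channel activations of the last
    convolutional stage are then converted into class-agnostic segmentation
    masks either by filtering, correlating and merging channels, or by k-means
    clustering of per-pixel feature vectors. Five recognition-oriented
    segmentation metrics (IoU, Dice, purity, entirety and loss-of-ground-truths)
    score the masks against reference label maps. A seeded synthetic-texture
    generator provides single-ingredient images and composite scenes with exact
    ground truth so the full pipeline is testable without any image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
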