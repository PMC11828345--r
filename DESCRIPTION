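Package: maensemble
Title: Mixed Attention Ensemble Classification of Esophageal Motility Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying high-resolution esophageal manometry (HREM)
    pressure-topography images into six motility categories (Achalasia type II,
    DES, EGJOO, IEM, Jackhammer and Normal) with a mixed attention ensemble:
    small convolutional backbones augmented with a softmax-normalised
    channel-and-spatial attention module (CSAE) and fused by a mixed voting
    mechanism that blends accuracy-driven individual weights with searched
    group weights. Includes a synthetic HREM-style image generator so the full
    pipeline is testable without clinical data, a stratified 6:2:2 split and
    eight-fold augmentation pipeline, confusion-matrix metrics with
    micro/macro/weighted aggregation, and a reproducible configuration-driven
    runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    nnet,
    EBImage,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
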