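Package: endofeat
Title: Hand-Crafted Visual Feature Maps for Endoscopic Bleeding Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes nine hand-crafted high-level visual feature activation
    maps of endoscopic bleeding (blood colour regions, smooth blood surfaces,
    clear region boundaries, relaxed red regions, dispersed blood, red colour
    domination, and blurriness) from colour endoscopy frames, together with
    automatic region-of-interest detection that removes the black frame border
    and device overlays. The feature maps can be fused with the RGB channels
    into 12-channel inputs for convolutional neural networks, including a
    function-preserving expansion of a first-layer kernel bank from 3 to 12
    input channels and output-averaging ensembling. Also provides
    feature-map-based weakly supervised bleeding localization with bounding-box
    intersection-over-union evaluation, a full set of ROC-based classification
    metrics with high-sensitivity and high-specificity operating points,
    dataset balancing and examination-grouped fold assignment, an image
    augmentation battery, and a seeded synthetic endoscopic frame generator
    used throughout the test suite.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, grDevices, tools, EBImage, png, tiff,
    jsonlite
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
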