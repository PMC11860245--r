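Package: stst
Title: Spatiotemporal Style Transfer for Dynamic Visual Stimulus Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesis of dynamic visual stimuli ("model metamers") whose
    spatial and temporal statistics are matched to target videos via
    two-stream style-transfer optimization: a spatial feature network and a
    motion-energy temporal network provide layer activations whose Gram
    matrices define texture losses, minimized per frame with multiscale
    (octave) normalized gradient descent, frame blending, mirror padding and
    3D color-distribution transfer. Includes a spatiotemporal phase-scrambling
    baseline, low-level feature analysis (intensity, contrast, pixel change,
    dense optical flow), color-distribution and palette descriptors, and
    representational similarity metrics (linear CKA, SSIM, conditional SSIM).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
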