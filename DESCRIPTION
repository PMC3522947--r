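Package: veinLDC
Title: Local Directional Codes for Finger-Vein Image Recognition
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extraction and matching of Local Directional Code (LDC) maps for
    finger-vein biometrics. Each interior pixel of a normalized grayscale
    capture is coded by its local gradient orientation, quantized into T
    dominant directions, in either the axis-aligned (LDC-00) or diagonal
    (LDC-45) neighbor convention. The package provides the full preprocessing
    chain (RGB-to-gray conversion, Sobel-based region-of-interest detection,
    bilinear size normalization to 96x64, min-max gray normalization),
    exact per-position code matching, biometric verification (ROC, equal
    error rate, FAR at zero FRR, FRR at zero FAR) and closed-set
    identification (ranks, cumulative match characteristic) protocols, a
    seeded synthetic vascular-image generator for end-to-end evaluation
    without access to a private capture database, and a command-line entry
    point tying the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
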