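Package: collmigr
Title: Quantification of Collective Cell Migration Under Directional Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify collective cell migration in confluent
    monolayers from time-lapse microscopy: particle image velocimetry (PIV)
    by windowed FFT cross-correlation with subpixel peak localization and
    normalized-median outlier filtering; migration order parameters
    (directionality along a guidance axis and the polarization/coordination
    order parameter), mean speed, x-velocity, neighbor velocity correlation
    and polar angle distributions; x-velocity and tissue-edge kymographs
    with texture-based tissue segmentation and leading/trailing edge
    tracking; and a wound-closure rate estimator. A Vicsek-style
    agent-based monolayer simulator and speckle-image renderer provide
    synthetic data with known ground truth, emulating tissues whose
    neighbor coordination is tunable (as by calcium-dependent E-cadherin
    adhesion) and optionally biased along a horizontal field axis (as in
    electrotaxis), so that every stage of the pipeline is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
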