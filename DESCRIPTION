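Package: thermotrack
Title: Contactless Estimation of Clothing Insulation and Metabolic Rate from
    Thermal Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@thermotrack.dev",
           role = c("aut", "cre"))
Description: Tools for estimating two personal thermal-comfort factors of
    office occupants -- clothing insulation rate (Icl, in clo) and metabolic
    rate (M, in W/m^2) -- from inputs derived from thermal infrared video.
    Implements SORT/DeepSort-style multi-person tracking-by-detection with a
    six-way clothing-by-posture taxonomy and category voting, skin and
    clothes region localization from pose keypoints, temperature
    accumulation and Icl computation from skin/clothes/operative temperature
    differences, activity-intensity features from bounding-box dynamics and
    optical-flow fields, probability-weighted metabolic-rate classification,
    CLEAR-MOT evaluation arithmetic, and a fully labelled synthetic thermal
    office-scene generator so the whole pipeline is testable without camera
    hardware.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    ranger,
    e1071,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
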