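Package: facepoi
Title: Points of Interest in Facial Feature Time Series via Online Change-Point Detection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Finds points of interest (PoI) in second-by-second facial feature
    recordings of care recipients, aimed at subjects whose expressions are
    attenuated by aging (micro expressions). Implements a two-stage change
    score built on the sequentially discounting autoregressive (SDAR) model
    with exponential forgetting, a composite "Smile scale" constructed from
    z-standardized landmark distances (mouth width, eyebrow height, eyes
    opening, mouth corner lowering), threshold-excursion extraction of PoI
    candidates, a raw-value threshold baseline, and recall/precision
    evaluation against annotated expression-change events within a tolerance
    window. Ships a synthetic episode generator producing labelled feature
    series so every stage can be exercised without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
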