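Package: whistlecee
Title: Multi-Scale Analysis of Dolphin Whistle Responses in Controlled
    Sonar Exposure Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies group-level whistle production of free-ranging
    dolphins during controlled exposure experiments (CEEs) with simulated
    mid-frequency active sonar, recorded on networks of drifting acoustic
    buoys.  Provides a synthetic-data generator for whistle trains with
    Markov vocal-state switching, drifting-buoy geometry and ping-triggered
    responses; great-circle buoy-to-group distances with a 1.6-km exclusion
    mask; per-second whistle counting from detection tables; binary
    segmentation changepoint detection in mean and variance; ping-aligned
    before/after window statistics at multiple temporal scales; and the
    statistical layer (negative-binomial mixed models, zero-inflated
    Gaussian models with AR(1) correlation, backward model selection,
    two-sample t tests) needed to test for behavioral responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    glmmTMB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
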