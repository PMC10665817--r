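Package: fiberflow
Title: Fiber Photometry Signal Correction and Behavioral Event Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-LED fiber photometry recordings and synchronized
    behavior: deinterleaving of frame-multiplexed excitation channels,
    standardized dF/F (zdF/F) computation via moving-average smoothing,
    adaptive iteratively reweighted penalized least squares (airPLS) baseline
    removal and non-negative L1-regularized reference fitting, behavioral
    bout and lick-event segmentation, peri-event alignment with windowed
    normalized AUC statistics, peri-event correlation classification and
    cross-correlation lag estimation, and optogenetics behavioral metrics
    (real-time place preference score, laser-epoch mobility metrics,
    baseline-normalized consumption metrics). Includes a synthetic-session
    generator with known latent structure for end-to-end parameter-recovery
    testing, and a pipeline runner with a session store.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
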