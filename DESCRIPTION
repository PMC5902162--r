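Package: spikedisc
Title: Windowed ROC Decoding of Visual Cortical Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for asking how brief a window of visual
    cortical activity suffices for perceptual discrimination. Provides
    behavioral readouts for a stop/no-stop visual foraging task (stop
    classification, choice accuracy, binomial confidence intervals,
    hold-time ideal-observer ROC), local field potential response-onset
    detection, per-unit windowed ROC discrimination of target versus
    distractor spike counts with rank-sum significance and
    Benjamini-Hochberg correction, first-spike latency statistics,
    Poisson spike-count modelling, orientation tuning and selectivity
    indices, and a shuffle-augmented population-pooling decoder. A
    synthetic-data module generates trial tables, spike trains, passive
    viewing responses and LFP traces with the statistical structure the
    analyses assume, so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
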