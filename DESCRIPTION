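Package: gazesharp
Title: Eye-Tracking Based Scoring of Rheumatoid Arthritis Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-joint gaze fixation durations recorded while reading
    hand and foot radiographs into modified van der Heijde Sharp (mvdH) scores
    for rheumatoid arthritis. Provides the mvdH joint inventory, a synthetic
    fixation-stream generator with ground-truth scores, assignment of fixations
    to joint regions of interest with an adjacent-joint non-analyzability rule,
    the fixation-duration to Sharp-point conversion, severity heatmaps and gaze
    plots, and agreement statistics against a reference reading (Cohen's kappa
    by class and dichotomized, intraclass correlation for replicate readings).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    png,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
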