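Package: swimtracker
Title: Swimming Motility Tracking and Fitness Statistics for Bacterial
    Host-Adaptation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies bacterial swimming motility from time-lapse
    microscopy and competitive fitness from colony-count data, as used in
    experimental-evolution studies of gut colonization. Implements subpixel
    spot detection (difference-of-Gaussians bandpass, intensity
    thresholding, radial-symmetry localization), nearest-neighbor track
    linking with minimum-length and duplicate-track filters, per-track
    speed statistics with a motile/non-motile cutoff and Wilson confidence
    intervals, competitive-index computation from CFU counts with
    flask-aware Dunnett contrasts, and serial-passage fluorescent-tag
    frequency summaries. Ships synthetic-data generators (run-and-tumble
    movies with ground truth, two-level competition count tables,
    growth-bottleneck passage trajectories) so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Matrix,
    tiff,
    yaml,
    multcomp,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'detect.R'
    'fitness.R'
    'io.R'
    'motility.R'
    'pipeline.R'
    'simulate-competition.R'
    'simulate-movie.R'
    'simulate-passages.R'
    'swimtracker-package.R'
    'track.R'
    'utils.R'
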