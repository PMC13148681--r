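Package: benthocam
Title: Quantitative Analysis of Fixed-Camera Seafloor Video and Co-Recorded Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify suspended-particle load and near-bed particle
    motion from fixed-camera time-lapse video of the seafloor, and to relate
    them to tidal forcing. Implements temporal-median background removal,
    binarization and connected-component particle statistics (area fraction,
    count, mean RGB intensity), an FFT cross-correlation particle image
    velocimetry (DPIV) core with subpixel peak fitting and normalized-median
    vector validation, circular reduction to a dominant flow per video
    segment, sea-level rate estimation and Pearson correlation with flow,
    raw periodograms with chi-squared confidence bounds, depth mapping of
    descent footage with RGB-versus-depth attenuation profiles, long-term
    Welch spectrograms of hydrophone audio, and summaries of manually
    annotated animal-detection tables. A seeded synthetic-scene generator
    produces tide-driven particle videos with full ground truth (particle
    positions, imposed flow, injected lens anomalies), recording schedules,
    sensor logs, and test audio, so every stage is testable end to end
    without the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    matrixStats,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
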