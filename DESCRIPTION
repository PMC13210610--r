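Package: strokestab
Title: Rowing-Stroke Technique Stability from Wearable Gyroscope Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying the stability of rowing-stroke
    technique from single-axis angular-velocity recordings made with a
    body-fixed MEMS gyroscope (e.g. a smartphone strapped to the upper back).
    Provides spectral (brick-wall Fourier) smoothing, stroke segmentation by
    negative-to-positive zero crossings, drive/recovery phase-duration
    statistics, an ensemble mean-stroke profile with point-wise dispersion, a
    period-normalized whole-stroke instability index, exact small-sample
    rank-sum and Wilcoxon signed-rank tests for longitudinal comparisons
    across training mesocycles, and a synthetic-data generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
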