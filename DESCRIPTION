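Package: wearcounts
Title: Open Activity-Intensity Counts and Classification from Raw Acceleration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes activity-intensity counts from raw tri-axial
    accelerometer signals at arbitrary sampling rates: band-pass filtering
    (a response-fitted fixed-bandwidth 8th-order filter or a modifiable
    4th-order Butterworth), rectification, saturation, deadband, count
    scaling, gain, 1-s epoch aggregation and the tri-axial vector-magnitude
    (VM3) count. Classifies counts into activity-intensity categories with
    configurable counts-per-minute cut-points (Freedson Adult VM3 shipped)
    by back-to-back 60-s epochs or by a per-second sliding window, and
    provides Bland-Altman and correlation agreement statistics for
    validating one count series against another. Includes a synthetic
    tri-axial signal generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
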