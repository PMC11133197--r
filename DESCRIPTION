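Package: blinkeo
Title: Blink Detection and Characterization from Eye-Openness Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects and characterizes eye blinks in eye-openness (eyelid
    aperture) signals from video-based eye trackers. Implements a velocity-based
    blink classifier built on Savitzky-Golay smoothing and differentiation with
    median-absolute-deviation (MAD) adaptive thresholds, a comparison detector
    that derives blinks from data loss in the pupil-size signal, one-to-one
    event matching with event-based F1 scores, data-quality metrics (data loss,
    RMS sample-to-sample precision), and a synthetic-recording simulator with
    ground-truth blink events for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
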