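Package: pdsense
Title: Passive Doppler Radar Breathing Detection and Activity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing pipeline for passive bistatic Doppler radar
    e-health sensing. Simulates paired reference/surveillance complex-baseband
    recordings of a DSSS illuminator scattered by a breathing chest or a moving
    person, computes batched cross-ambiguity (delay-Doppler) maps, cancels
    direct-path interference with a CLEAN step, assembles Doppler spectrograms,
    and switches between a breathing branch (micro-Doppler extraction,
    Savitzky-Golay smoothing, FFT rate estimation, chest-belt evaluation) and an
    activity branch (SVD/PCA/physical features with a one-vs-one SVM over six
    activities of daily living).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
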