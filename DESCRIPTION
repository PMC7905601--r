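Package: seasong
Title: Seasonal Analysis of Birdsong Structure, Brain Receptor Densitometry,
    and Territorial Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible computational pipeline for studies of seasonal
    song and territoriality in songbirds with three-part strophes (part A,
    an atonal part B, and part C, as in the black redstart). Provides
    amplitude-trigger sound-event detection with minimum-gap merging, an
    element counter with a relative-threshold/hold-time rule, strophe
    parsing into parts A, B and C, spectrogram-based spectral measurements
    (band limits, durations, the A-B pause), a nine-quantity sonogram
    descriptor (average, modal and fundamental frequency, Wiener entropy,
    duration, and frame-wise standard deviations), incremental-split k-means
    syllable-repertoire clustering, autoradiogram optical densitometry with
    adjacent-background subtraction and serial-section nucleus volume
    reconstruction, and the seasonal statistics layer (stage linear models,
    stage-by-area mixed models with likelihood-ratio tests, Poisson song-rate
    models, post-hoc corrections, Cohen's d and Pearson effect sizes).
    A synthetic-data generator produces audio, section images and stage
    tables with known ground truth so every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    emmeans,
    car,
    mgcv,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
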