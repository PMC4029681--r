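Package: wheezer
Title: STFT-Based Detection of Asthmatic Wheezing in Respiratory Sounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection of asthmatic wheezing in respiratory sound
    recordings using short-time Fourier transform features and decision-tree
    classification. Implements four segment-wise detectors (spectral-crest
    tracking with moment- or energy-based crest models, tonality tracking,
    and spectral-peak entropy change detection), leave-one-out grid-search
    training with a sensitivity-times-specificity objective, segment-wise and
    respiratory-phase-wise scoring, an exact operation-count model of the
    feature-extraction pipeline for embedded complexity budgeting, and a
    seeded generator of annotated synthetic respiratory recordings for
    testing detectors without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
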