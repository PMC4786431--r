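Package: burstpause
Title: Burst-and-Pause Firing and Dendritic Calcium Transient Analysis for
    Larval Nociceptor Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of "burst and pause" firing and dendritic
    calcium transients in Drosophila class IV nociceptive neurons.
    Implements spike-train firing metrics (sliding rectangular-window rates,
    Gaussian-kernel spike density, derivative-peak burst counting,
    stimulus-locked frequency change), an unconventional-spike (US) triplet
    classifier with parameter sweeps, a FRET ratiometric imaging pipeline
    (binary-mask segmentation, ROI signal/background extraction, ratio
    traces, peak ratio change, transient classification, photobleach
    baseline estimation), electrode-resistance Arrhenius thermometry and an
    IR-laser power-to-temperature model, supporting inferential statistics,
    and synthetic-data generators that emulate the statistical structure of
    the recordings so every stage of the pipeline can be exercised and
    validated end-to-end on data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
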