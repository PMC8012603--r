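Package: pcfret
Title: Multiplexed FRET Readout via Donor Photochromism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies Foerster resonance energy transfer (FRET) from
    sensitized-emission acquisitions and separates two or more spectrally
    identical FRET pairs using the light-induced on/off switching
    (photochromism) of their donor fluorophores.  Provides correction-factor
    based FRET efficiency estimation, photoswitching-ratio calibration with
    orthogonal distance regression, an iterative linear-unmixing solver for
    mixed on/off acquisitions, a Poisson photon-noise Monte-Carlo validation
    study, and downstream live-cell time-lapse analysis (photobleaching
    baseline correction, percent-increase responses, onset times and
    k-means response classification).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
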