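Package: radarheart
Title: Heart Sound Detection from Continuous-Wave Radar Interferometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for touch-free heart sound monitoring with a Six-Port
    continuous-wave radar interferometer. Converts four-channel baseband
    voltages into chest displacement via ellipse-fit I/Q compensation and
    arctangent demodulation, separates respiration, pulse-wave, heart-sound
    and ECG bands with fourth-order Butterworth filters, segments first and
    second heart sounds (S1/S2) with a duration-dependent (hidden semi-Markov)
    logistic-regression decoder, and evaluates beat timing against ECG
    references (F-score, interbeat-interval RMSE). Includes morphology
    comparison between radar and phonocardiograph segments, respiratory
    peak-envelope and S2-split analyses, and a fully synthetic multichannel
    scene generator with ground-truth fiducials for end-to-end testing
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
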