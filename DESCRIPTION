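Package: revalpha
Title: Reversal-Related EEG Alpha Desynchronization: Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of event-related alpha-band
    desynchronization around perceptual reversals in multistable perception
    EEG experiments. Provides a synthetic continuous-EEG generator with
    event-locked alpha suppression and common artifact types, response-locked
    epoch segmentation with amplitude-based artifact rejection and seeded
    epoch-count equalization, complex Morlet wavelet time-frequency
    decomposition via frequency-domain convolution with decibel baseline
    normalization against perceptually stable epochs, and the group-level
    statistical battery used in aging studies of bistable perception:
    mixed-design ANOVA with Greenhouse-Geisser correction and linear trend
    contrasts, planned paired comparisons with Hedges g_av, Mann-Whitney U
    and independent t group comparisons, and dwell-time regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
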