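Package: fatiguenet
Title: Small-World Brain Functional Network Analysis of EEG Mental Fatigue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how mental fatigue reshapes EEG functional
    connectivity and small-world network organization. Implements histogram
    mutual information with Miller-Madow bias correction between all pairs of
    scalp electrodes, FFT band decomposition into the classical EEG rhythms,
    the (theta + alpha1 + alpha2)/beta spectral fatigue ratio, network
    binarization by weight threshold or fixed mean degree, clustering
    coefficient, characteristic path length and the small-world index against
    Maslov-Sneppen degree-preserving null ensembles, one-way ANOVA based
    rhythm selection, and a synthetic multichannel EEG generator with a
    controlled fatigue trajectory so the whole pipeline is testable with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
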