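Package: lzdiversity
Title: Lempel-Ziv Signal Diversity Analysis for Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes single-channel (LZs) and spatio-temporal (LZc)
    Lempel-Ziv signal diversity from Hilbert-envelope-binarized EEG
    epochs, with surrogate (shuffle) normalization. Includes the full
    supporting pipeline: a synthetic multichannel EEG session generator
    with controllable narrowband/broadband structure and vigilance
    drift, an FIR preprocessing chain (filter bank, downsampling,
    epoching, automated artifact rejection, re-referencing and channel
    interpolation), and the repeated-measures statistical battery used
    in signal-diversity studies (Friedman omnibus, Wilcoxon signed-rank
    post hocs with Bonferroni-Holm correction, JZS Bayes factors,
    time-on-task quartile analysis, and cluster-based permutation
    topography tests). Minimal EDF and BrainVision readers/writers are
    provided for interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
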