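Package: microdyn
Title: EEG Microstate Segmentation and Temporal Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resting-state EEG microstate analysis: global field power (GFP)
    peak detection, polarity-invariant atomize-and-agglomerate hierarchical
    clustering (AAHC) into canonical microstate classes, back-fitting of group
    template topographies, temporal properties (duration, occurrence,
    transition matrices), and an information-theoretic characterization of the
    microstate label sequence (Markovianity of orders 0-2, stationarity and
    symmetry of the transition matrix, and the autoinformation function), with
    cohort-comparison statistics (pooled t-tests, Bonferroni-Holm correction,
    Cohen's d). Includes a semi-Markov synthetic-EEG generator with planted
    topographies so every stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
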