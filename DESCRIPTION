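Package: usvsyntax
Title: Syllable Detection and Syntax Analysis of Mouse Ultrasonic Vocalizations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the song-like ultrasonic vocalizations (USVs) of
    adult mice. Detects and classifies syllables (simple, up-jump, down-jump,
    multi-jump) from high-sample-rate recordings via spectrogram thresholding and
    pitch-jump analysis, segments syllables into song bouts, computes sequence
    summary statistics, and tests differences in first-order syllable transition
    dynamics between groups or social contexts with a two-stage procedure:
    per-transition Wilcoxon rank tests combined by the truncated product method
    of Zaykin and calibrated against a permutation Monte Carlo null, with
    Benjamini-Hochberg correction across combined tests. Includes a synthetic
    cohort and waveform generator with known ground truth, syntax-diagram export
    in Graphviz DOT format, and a manifest-driven pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
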