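Package: seqphase
Title: Phase-of-Firing Analysis of Sequence Working Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether the theta phase at which neurons fire
    encodes the position of items held in sequence working memory. Provides
    a synthetic session generator (trial tables, theta-band local field
    potentials, von Mises phase-locked Poisson spike trains), Morlet-wavelet
    spectral decomposition with instantaneous phase extraction, circular
    statistics including the circular variance explained (V_ex) with
    label-permutation nulls, phase-order classification under rotation
    equivalence with a phase-reset model predicting order from stimulus
    timing and oscillation frequency, kernel-SVM position decoding with
    shuffle nulls, and a Dale-constrained firing-rate recurrent network
    trained on a sequence match/non-match task with an oscillation-frequency
    regularizer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
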