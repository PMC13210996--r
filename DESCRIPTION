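Package: radarpcg
Title: Contactless Phonocardiography from Doppler Radar
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recovering heart-sound (phonocardiogram-like) waveforms
    from continuous-wave Doppler-radar baseband recordings. Implements a
    physically motivated simulator of radar chest-displacement measurements,
    the standard pre-processing chain (geometric ellipse-fitting I/Q
    compensation, differentiate-and-cross-multiply phase unwrapping,
    displacement conversion, resampling, band-pass filtering and
    normalization), a multitask self-attention 1D U-Net that jointly
    reconstructs the waveform, its homomorphic envelope and a four-state
    cardiac-phase segmentation, the multitask training objective, and the
    evaluation metrics (log-spectral distance, envelope correlation,
    micro/macro F1 and event-based S1/S2 scoring).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
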