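Package: opmburst
Title: Attention-Modulated Beta Bursts in Simulated OPM-MEG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and source-space analysis of pan-spectral beta bursts
    in optically pumped magnetometer (OPM) magnetoencephalography. Generates a
    braille tactile-attention paradigm and ground-truthed synthetic triaxial
    OPM recordings over a spherical volume conductor; preprocesses sensor data
    (Welch spectra, bad-channel and bad-trial rejection, homogeneous field
    correction); reconstructs regional virtual electrodes with a Tikhonov
    regularised LCMV beamformer; computes Hilbert-envelope contrast-to-noise
    ratios against rest baselines; detects bursts with a univariate
    time-delay-embedded 3-state Gaussian hidden Markov model; and contrasts
    burst probability, count, amplitude and duration between attention
    conditions with exact Wilcoxon sign-rank tests under Benjamini-Hochberg
    false discovery rate control.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
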