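Package: pinprickEEG
Title: Pinprick Somatosensory Evoked Potential and Time-Frequency EEG Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing electroencephalographic
    responses to mechanical pinprick stimulation of the hand, as used to study
    somatosensory processing after stroke. Provides a synthetic-cohort
    generator with a known ground truth (stimulus protocol, 1/f background
    EEG, biphasic evoked responses, band-limited oscillatory power
    modulations, linked clinical scores), continuous-EEG preprocessing
    (zero-phase FIR band-pass, bad-channel detection, common-average
    re-referencing, amplitude-based segment rejection), time-domain measurement
    of the negative-positive somatosensory evoked potential at the central
    electrodes, complex Morlet wavelet time-frequency decomposition with
    decibel baseline normalisation, a circular-shift surrogate bootstrap that
    discovers event-related (de)synchronisation regions of interest, and the
    group-level and clinical-association statistical models (one-way ANOVA
    with Tukey post-hoc contrasts and Cohen's d, linear mixed models of
    region-of-interest power, and backward-stepwise clinical regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
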