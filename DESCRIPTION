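Package: prr
Title: Respiration-Entrained Rhythm Analysis for Awake-Mouse LFP and Spike Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for respiration-entrained slow oscillations in
    prefrontal local field potentials and their coupling to faster rhythms and
    to single-unit discharge. Implements multitaper power spectral density with
    1/f normalization and band-peak extraction, LFP-respiration magnitude-squared
    coherence, n:m phase-phase coupling profiles with time-shift surrogates,
    Kullback-Leibler phase-amplitude modulation index and comodulograms,
    rms-threshold extraction of theta-rich epochs, waveform-based cell-type
    classification, and spike-phase entrainment statistics (Rayleigh test,
    circular means, population summaries). A synthetic-session generator with
    full ground-truth parameter records makes every stage testable by
    construction-recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
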