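Package: apenlfp
Title: Approximate Entropy Analysis of Stimulus-Evoked Hippocampal Gamma
    Oscillations
Version: 0.1.0
Authors@R:
    person("apenlfp", "developers", email = "apenlfp@example.org",
           role = c("aut", "cre"))
Description: Pipeline for quantifying the regularity of tetanus-evoked
    hippocampal field-potential gamma oscillations with approximate entropy
    (ApEn). Provides a phenomenological generator of stimulus-evoked local
    field potentials with condition-dependent regularity (control, nicotine,
    washout), the preprocessing chain used in slice electrophysiology
    (stimulus-artifact blanking, anti-aliased decimation to 2 kHz, piecewise
    linear detrending, 30-300 Hz zero-phase band-pass), isolation and
    spectral verification of the 150-250 ms post-stimulus gamma segment, a
    from-scratch ApEn implementation with a brute-force oracle, and paired
    within-slice group comparisons (means +/- SEM, paired t and Wilcoxon
    signed-rank tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
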