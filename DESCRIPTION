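Package: sepkit
Title: Preprocessing Comparison Pipelines for Somatosensory Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how EEG preprocessing choices change the measured
    amplitude of median-nerve somatosensory evoked potentials (SEPs).
    Implements Kaiser windowed-sinc FIR and Butterworth IIR zero-phase
    filtering, a simplified standardization stage (bad-channel flagging,
    line-noise regression, average reference), stimulus-locked epoching with
    baseline correction, five sliding-window artifact rules with a
    stimulus-window exclusion mask, ICA component removal by back-projection,
    N30 peak-to-peak quantification, and a gamma log-link random-intercept
    model with estimated marginal means and ratio contrasts. A synthetic
    multi-channel EEG generator with known ground truth makes the full
    factorial comparison (filter class x passband x ICA) testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    emmeans,
    withr
Config/testthat/edition: 3
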