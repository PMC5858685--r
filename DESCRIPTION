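Package: qbif
Title: Quick Estimation of Band Importance Functions for the Speech
    Intelligibility Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating individualized Speech Intelligibility Index
    (SII) parameters -- octave-band spectral weights (the band importance
    function), the speech recognition threshold, and the psychometric slope --
    from trial-by-trial speech recognition data.  Implements a Bayesian
    adaptive procedure that selects each trial's stimulus (a target-to-masker
    ratio and a subset of octave bands) by minimizing the expected entropy of
    the posterior parameter distribution, maintained via ridge-penalized
    logistic regression.  Includes non-adaptive baseline sampling strategies,
    simulated listeners driven by the classical asymmetric SII transfer
    function for validation studies, and the octave Butterworth filterbank
    signal chain used to synthesize band-limited speech-in-noise stimuli.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
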