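Package: mechdelay
Title: Mechanical Representation of Visuomotor Time Delays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis tools for visuomotor tracking experiments in
    which a time delay between hand and cursor is approximated by an equivalent
    spring-mass-damper system. Provides the delay and second-order Taylor
    (mechanical) operators and their transfer functions, forward simulation of
    delayed and mechanical cursor dynamics, feed-forward internal-model simulators
    (delayed-state and mechanical representations) with exponential trial-by-trial
    adaptation and schedule fitting, per-trial kinematic analysis (plateau RMSE,
    segment cross-correlation lags, after-effects, double-exponential learning
    curves, reversal-point movement amplitude), grip-force/load-force coupling
    analysis with virtual spring-force correction, and a synthetic-subject
    generator with ground-truth sidecars for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
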