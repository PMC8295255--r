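Package: neurotimescales
Title: Temporal Stability of Neural Representations Along Visual Cortical
    Hierarchies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for estimating the characteristic timescales of
    dynamic visual stimuli and of the neuronal population responses they
    evoke: pixel-, response- and intrinsic-correlation functions with
    exponential / damped-oscillation model fits selected by an extra
    sum-of-squares F-test; cross-temporal linear decoding of population
    activity with pseudopopulation construction, trial shuffling and the
    intrinsic-correlation performance gain; ordinary-least-squares and robust
    Theil-Sen regression layers with stratified percentile bootstrap; and a
    locomotion-state (rest/run) partition analysis. Ships a synthetic-data
    generator (autoregressive movies, phase-scrambled and white-noise stimuli,
    doubly stochastic Poisson spike populations, wheel-velocity traces) with
    known ground truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
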