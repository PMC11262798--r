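Package: thetabmi
Title: Closed-Loop Theta-Coherence Brain-Machine Interfacing and Dual-Site
    LFP Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for coherence-contingent closed-loop experimentation on
    dual-site local field potentials (LFPs): streaming Welch
    magnitude-squared coherence with artifact gating, per-subject threshold
    calibration, and coherence-triggered trial scheduling with yoked
    controls; together with an offline analysis suite covering multitaper
    spectral power, event-locked coherograms, Geweke bivariate and
    pairwise-conditional spectral Granger causality with BIC order
    selection, spike-phase entrainment (Rayleigh test, bootstrapped mean
    resultant length), Morlet-wavelet spike-field coherence, and behavioral
    quantification (IdPhi head-movement complexity, distance traveled, time
    to choice). A synthetic-data module generates coupled theta
    oscillators, movement artifacts, phase-locked spike trains and position
    trajectories so the full pipeline runs without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
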