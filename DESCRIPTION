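Package: pulsedepth
Title: Simulation and Analysis of Adaptive Hold-Down Pressure Pulse Wave Acquisition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free digital twin of a radial pulse tonometry instrument.
    Simulates synthetic wrist subjects with a depth-dependent pulse amplitude
    envelope, runs both the classical fixed-range five-step hold-down pressure
    protocol (40-240 mmHg) and an adaptive protocol that finds each subject's
    own perceptible pressure range by a continuous slow descent sweep with
    beat-peak detection, then measures five equal pressure steps on ascent.
    Provides P-H curve construction by natural cubic spline, the coefficient of
    floating and sinking pulse (CFS) with floating/sinking classification, a
    weak-minus-strong pulse pressure index, method-comparison statistics
    (paired t-test, Pearson correlation), a packaged 20-subject reference
    cohort, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
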