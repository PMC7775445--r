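Package: saliencecpt
Title: Simulation and ERP Analysis of the Salience Continuous Performance Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the Salience Continuous Performance Task (Salience
    CPT), a 'not-X' Go/NoGo paradigm extended with rare physically salient
    Go stimuli. Generates constrained pseudo-randomized trial sequences,
    simulates synthetic cohorts (EEG epochs with condition-specific
    P1/N2/P3 components, 1/f plus white noise, and behavioral responses)
    with known ground-truth effects, preprocesses epochs (re-referencing,
    zero-phase band-pass filtering, downsampling, baseline correction),
    quantifies ERP components by signed-area amplitude and fractional-area
    latency together with their single-trial variability, computes
    behavioral performance measures, and runs a normality-gated partial
    correlation battery with outlier exclusion, Bonferroni correction,
    extreme-group contrasts, polynomial fits, and a minimum-detectable-
    correlation power computation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    car,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
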