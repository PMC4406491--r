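Package: isofatigue
Title: Simulation and Analysis of Repeated Maximal Isokinetic Contraction Fatigue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to simulate and analyse neuromuscular fatigue experiments
    built around repeated maximal isokinetic knee extensions. A synthetic-data
    generator produces torque, angular-velocity and surface-EMG traces with
    known ground truth (per-set declines, evoked twitch responses, oxygen
    uptake kinetics, blood lactate). Extraction routines recover mechanical
    variables (mean and peak torque, rate of torque development, voluntary
    activation, evoked twitch metrics), EMG amplitude variables (RMS envelope,
    rate of EMG rise, M-wave amplitude, M-max normalisation) and a Morlet
    wavelet time-frequency analysis yielding the instantaneous mean frequency
    of the EMG over 75-ms bins. An aggregation and statistics layer implements
    set-block averaging, standardized and forward-stepwise regression,
    one-way repeated-measures ANOVA with Tukey post hoc tests, and
    mono-exponential oxygen-uptake fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
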