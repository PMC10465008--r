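Package: pangotherm
Title: Heterothermy Analysis of Free-Ranging Pangolin Body Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse biologged core body temperature of free-ranging
    Temminck's pangolins in a semi-arid environment: logger calibration and
    clock-drift correction, 24-h body temperature summaries (minimum, maximum,
    mean and amplitude), burrow emergence and return detection from abrupt
    body temperature notches, and piecewise linear-spline mixed models linking
    the 24-h metrics to photoperiod, prey abundance, black globe temperature
    and emergence time, with AIC-driven breakpoint selection, cluster-robust
    standard errors and a negative binomial model for pitfall-trap prey counts.
    Includes a calibrated synthetic-data generator that reproduces the
    statistical structure of the study system so the full pipeline is testable
    without the (undeposited) field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    sandwich,
    zoo,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
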