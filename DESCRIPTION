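Package: cyclonemort
Title: Tropical Cyclone Exposure and Excess Mortality Analysis
Version: 0.1.0
Authors@R:
    person("Cyclone", "Epi Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of tropical-cyclone mortality impacts. Stage one
    converts best-track storm records into gridded maximum sustained winds with a
    parametric Holland wind-field model, derives per-location exposure records
    (34-knot threshold, hit day t0, cumulative rainfall), fits a mixed Poisson
    baseline for expected daily deaths on control periods, and estimates the
    storm-specific relative increase in mortality with a spline that allows a
    discontinuity on the hit day, yielding the period of concern (POC), excess
    deaths and relative risks. Stage two pools the log relative risks with a mixed
    meta-regression (storms nested within locations, known within-event variances,
    REML) and produces exposure-response curves for windspeed, rainfall and
    calendar year. A synthetic-data module generates storms, populations, rainfall
    and mortality series with known injected effects so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
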