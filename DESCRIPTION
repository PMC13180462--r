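Package: citsim
Title: Monte Carlo Evaluation of Control-Group Formulations in Interrupted Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation framework for comparing segmented-regression model
    formulations that embed a control series in interrupted time series (ITS)
    designs. Provides a configurable data-generating process for two-group
    panels with a mid-series level-change intervention, a post-period common
    confounder and group-specific time-varying unobservables; estimators for
    controlled ITS, difference-in-differences, ITS of the between-series
    difference, control-as-covariate and uncontrolled designs, with optional
    restricted cubic splines of time; robust variance estimation (White,
    Driscoll-Kraay, panel feasible GLS, regression with AR(1) errors); a
    pre-intervention parallel-trend test with power estimation; and a Monte
    Carlo engine scoring each estimator by bias, SE ratio and coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
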