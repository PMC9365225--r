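Package: hemseval
Title: Evaluation of Regional HEMS Coordination by Interrupted Time Series
    and Convex-Hull Service Areas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating organisational interventions in helicopter
    emergency medical services (HEMS). Implements segmented interrupted
    time-series analysis of monthly mean response times with a winter
    indicator and moving-average error structures (maximum likelihood,
    AICc-based error-model selection, counterfactual prediction), convex-hull
    geodesic service-area analysis per helicopter base with 95th-percentile
    distance filtering and equal-area km2 computation, in-flight-scramble
    classification, inclusion/exclusion filtering with audit tallies, and a
    pre/post descriptive-comparison battery (chi-square, Mann-Whitney,
    Welch/Student t, Hodges-Lehmann median-difference confidence intervals).
    A mission-level synthetic data generator with configurable level/slope
    intervention effects, seasonality and MA(1) month-level autocorrelation
    makes every stage testable without access to operational registries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    nlme,
    optparse
Config/testthat/edition: 3
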