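Package: cgfdist
Title: Continuous Estimation of Child Growth Failure Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates entire distributions of child anthropometric z-scores
    (height-for-age, weight-for-height, weight-for-age) rather than single
    dichotomous prevalence thresholds. Provides a ten-family method-of-moments
    ensemble density with global weight fitting against microdata, three-stage
    spatiotemporal Gaussian process regression (covariate prior, space-time-age
    residual smoothing, Gaussian-process draws), variance recovery that
    reconciles modelled mean z-scores with threshold prevalences into a single
    continuous curve per location-year-age-sex draw, and downstream analyses:
    multi-severity prevalence integration, draw-level relative change,
    annual-change disruption analysis with Kolmogorov-Smirnov comparisons, and
    monotone quadratic-spline meta-regression of prevalence on the universal
    health coverage index. A synthetic-data module generates location
    hierarchies, true growth surfaces, microdata and tabulated surveys,
    covariates, and populations with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    flexsurv,
    lme4,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
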