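Package: cropdbn
Title: Dynamic Bayesian Network Forecasting of Sigmoid-Type Crop Growth
    with Missing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a control-driven linear-Gaussian state-space model (a
    dynamic Bayesian network) to sigmoid-type crop growth indicators such
    as leaf area index (on its reciprocal scale) and evapotranspiration,
    driven by greenhouse environment variables (growing degree days,
    solar irradiance). Parameters are learned by exact
    expectation-maximization with missing-at-random observations
    marginalized out of the likelihood, using Kalman filtering and
    Rauch-Tung-Striebel smoothing with time-varying transitions.
    Includes multi-step-ahead forecasting with frozen control inputs,
    analytic benchmark models (Boltzmann-sigmoid leaf area index,
    simplified radiation-based evapotranspiration, linear regression),
    growing-degree-day utilities, and a synthetic greenhouse data
    generator for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
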