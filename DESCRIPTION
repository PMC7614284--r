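Package: chronicrates
Title: Bayesian Multistate Estimation of Chronic Disease Incidence and
    Case Fatality from Aggregate Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates age-specific disease incidence, case fatality and
    remission rates from aggregate count data on incidence, prevalence,
    mortality and remission, using a Bayesian continuous-time illness-death
    (three-state) model.  Age dependence is modelled by penalised thin-plate
    spline curves with the degree of smoothness estimated from the data;
    rates can be related across geographical areas through a hierarchical
    model, across genders through additive effects, and through calendar
    time via published age-specific risk ratios.  Two inference engines are
    provided: full posterior sampling by adaptive Markov chain Monte Carlo,
    and a fast posterior-mode fit with a multivariate normal (Laplace)
    approximation.  Model checking tools include fitted-versus-observed
    comparison tables, conflict p-values for consistency between data
    sources, and leave-one-out expected log predictive density via
    Pareto-smoothed importance sampling.  Utilities convert published
    estimates with interval bounds into equivalent binomial counts,
    disaggregate five-year age groups to single years of age with a
    penalised composite-link model, and derive remission rates from
    ten-year survival probabilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
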