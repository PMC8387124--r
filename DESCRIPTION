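Package: atmort
Title: Age Trajectories of Child Mortality by the Halley Method
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for constructing and modelling the age trajectory of
    mortality (ATM) in childhood from death counts and census-style
    population counts. Deaths and exposures from several countries and
    calendar years are pooled into one hypothetical population (the Halley
    method) to obtain age-specific mortality rates per person-year,
    including the four sub-year infant age categories used by the WHO
    mortality database. The rate trajectory is then assessed in the
    log-log scale by a three-stage model selection: a quadratic curvature
    test, a two-parameter linear fit, and a nested F-test of the
    inverse-proportion law mu(x) = mu1/x. A bending-hazard model derived
    from a congenital-frailty theory, an individual-based frailty
    simulator with a quadrature mixture-hazard oracle, and a synthetic
    WHO-layout data generator with Poisson count noise make every stage
    of the pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
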