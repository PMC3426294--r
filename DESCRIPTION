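Package: epichaos
Title: Stochastic Galerkin Polynomial Chaos for Epidemic Compartmental Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Intrusive generalized polynomial chaos for compartmental
    epidemic models described by ordinary differential equations with
    polynomial right-hand sides and uniformly distributed transmission
    parameters. Builds truncated multivariate Legendre chaos bases and
    their inner-product tensors, assembles and integrates the stochastic
    Galerkin auxiliary system for the chaos coefficients, and extracts
    mean trajectories, variances, standard-deviation bands, and
    variance-based (Sobol) first-order sensitivity indices directly from
    the expansion coefficients. Includes a Monte Carlo propagation and
    pick-and-freeze Sobol oracle for cross-validation, a bundled
    normal-weight/overweight/obese population dynamics model, and a
    configuration-driven pipeline with tidy CSV outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
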