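Package: fatecircuit
Title: Bistability and Degenerate Bifurcation in a Two-Gene Fate-Decision Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemical-kinetics models of the mutual-repression /
    self-activation two-gene circuit that drives binary cell fate decisions,
    their rapid-equilibrium reduction to a shared generic two-variable
    dynamical system, closed-form steady-state enumeration with
    eigenvalue-based stability classification, bifurcation analysis in the
    cross-repression to self-saturation ratio q = c/b, the degenerate
    steady-state manifold arising at b = c, and Euler-Maruyama simulation of
    the additive-noise stochastic system with stationary-density and
    attractor-mode estimation. Results are returned as tibbles with broom-style
    tidy() and glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
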