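Package: cvsude
Title: Hybrid Neural Ordinary Differential Equation Modelling of the
    Cardiovascular System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A closed-loop lumped-parameter (pressure-volume) model of the
    human cardiovascular system with ventricular interaction through the
    septum and pericardium, following the minimal haemodynamic model of
    Smith et al. (2004) <doi:10.1016/j.medengphy.2003.10.001>. The septum
    free-wall volume is located by a Newton-Raphson root solve embedded in
    the ODE right-hand side. The package simulates synthetic haemodynamic
    time series, embeds a small fully connected neural network in place of
    the ventricular-interaction terms (a hybrid neural ODE / universal
    differential equation), trains it by backpropagating a pooled
    mean-squared-error loss through a fixed-step integration of the hybrid
    system, distils the trained network into closed-form expressions by
    genetic-programming symbolic regression, and evaluates the extrapolation
    quality of the resulting partially learned mechanistic model against the
    ground-truth simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
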