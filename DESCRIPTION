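Package: udeuq
Title: Epistemic Uncertainty Quantification for Universal Differential Equations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing epistemic (parameter) uncertainty in universal
    differential equations (UDEs), hybrid models that embed a neural network
    inside a mechanistic ordinary differential equation. Provides a synthetic
    SEIR data generator with time-varying transmission rates and Gaussian or
    negative-binomial observation noise, a differentiable UDE objective
    (forward-sensitivity gradients through a fixed-step Runge-Kutta solver),
    and three uncertainty-quantification back-ends: multi-start ensembles with
    likelihood-ratio subselection, Markov chain Monte Carlo (No-U-Turn sampler
    and parallel tempering), and mean-field variational inference. A shared
    evaluation layer scores parameter and trajectory coverage against the known
    data-generating process.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
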