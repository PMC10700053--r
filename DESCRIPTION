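Package: breedoptim
Title: Simulation-Based Optimization of Breeding Program Design via Kernel Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for numerically optimizing the design of animal breeding
    programs when the objective can only be observed through stochastic
    simulation. Implements a progeny-testing dairy scheme simulator under the
    infinitesimal model with pedigree-based kinship tracking, Nadaraya-Watson
    kernel regression with a product Gaussian kernel to smooth noisy
    realizations of genetic gain and inbreeding into an estimable composite
    target surface, and an iterative optimizer that narrows the search box and
    halves the bandwidth until the estimated optimum stabilizes under an
    annual budget constraint. Also provides a piecewise-linear interpolation
    baseline, bootstrap comparison of smoothing methods, and analyses of
    optimum stability versus the number of simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
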