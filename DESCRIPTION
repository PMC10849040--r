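Package: excitondyn
Title: Excitation Energy Transfer by Surface Hopping and Perturbative Rate Theories
Version: 0.1.0
Authors@R: person("Exciton", "Dynamics Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Simulates excitation energy transfer in Frenkel-exciton models of
    photosynthetic pigment assemblies. Implements the multi-state mapping
    approach to surface hopping (MASH) with cap, focused and equivariant
    initial conditions as well as the original two-state prescription, plus
    Redfield (non-secular and secular) and Foerster perturbative rate
    theories, bath correlation and cumulant lineshape functions, harmonic
    bath discretization, and the exponential rate-extraction protocol used
    to compare the methods on a two-site dimer and on the eight-site
    Fenna-Matthews-Olson complex with static disorder.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
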