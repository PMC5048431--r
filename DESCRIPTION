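Package: isingtriad
Title: Network, Latent-Variable and Common-Effect Representations of the
    Ising Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for the Ising model for binary (+1/-1) variables and its
    two mathematically equivalent reparameterisations: a multidimensional
    item response theory (latent-variable) form obtained by Gaussian
    linearisation of the quadratic interaction term, and a collider
    (common-effect) form in which conditioning on all effect variables being
    present reproduces the Ising distribution through endogenous selection.
    Provides exact enumeration of the probability mass function, eigenvalue
    based conversions between the three parameterisations, Gauss-Hermite
    marginalisation of the latent form, seeded exact and Markov chain Monte
    Carlo samplers under each representation, and a verification engine that
    certifies the distribution-level equivalence in total variation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
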