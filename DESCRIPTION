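Package: saskit
Title: Small-Angle Scattering Models, Size-Distribution Inversion and
    Numerical Structure Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing one-dimensional small-angle scattering
    curves: analytical form factors (sphere, Debye-Anderson-Brumberger) and
    their projected correlation functions; flexible size distributions
    including the quantile-parameterized metalog family with quantile-space
    form-factor integration; model-free size-distribution retrieval by
    Tikhonov regularization and four expectation-maximization schemes with
    L-curve selection of the regularization weight; multiple-scattering
    intensities computed through numerical Hankel transforms; and a numerical
    Ornstein-Zernike solver for spherically symmetric pair potentials with
    Percus-Yevick, hypernetted-chain, MSA and modified-MSA closures, verified
    against the analytical hard-sphere structure factor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
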