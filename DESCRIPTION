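Package: lcgp
Title: Low-Complexity Gaussian Process Regression with Differential-Operator Eigenbases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reduced-rank Gaussian process regression built from truncated
    Karhunen-Loeve (Mercer) expansions whose eigenfunctions are closed-form
    eigenbases of classical differential operators: a Dirichlet sine basis
    with a Matern-type spectrum, and the Legendre, Laguerre, Hermite,
    Chebyshev and Jacobi orthogonal-polynomial families. Fitting costs
    O(N m^2) time and O(m^2) memory for N observations and m basis
    functions, hyperparameters are learned by gradient ascent on the
    approximate log marginal likelihood, and an exact O(N^3) Gaussian
    process implementation is included as a small-N oracle and baseline.
    Ships Karhunen-Loeve prior samplers (including the Brownian motion and
    Brownian bridge series), synthetic-benchmark generators, ISE and
    R-squared metrics, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
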