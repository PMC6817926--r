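Package: wavepred
Title: Exact Traveling-Wave Solutions of a Diffusive Two-Predator/One-Prey Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs, from first principles, the exact traveling-wave
    solution families of a diffusive predator-prey reaction-diffusion system
    with a two-predators/one-prey interaction term. Implements the (G'/G)-
    expansion and generalized auxiliary-equation methods on top of an exact
    rational polynomial-algebra engine (homogeneous balance, coefficient
    collection, branching triangular solver, symbolic back-substitution
    proofs), residual operators for the reduced traveling-wave system, a
    method-of-lines finite-difference simulator of the full PDE system with
    manufactured-solution convergence checks and front-speed estimation, and
    reproduction of the reference parameter studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
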