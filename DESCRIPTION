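Package: wmforce
Title: Temporally Restricted FORCE Training and Attractor Analysis of
    Working-Memory Rate Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Trains recurrent firing-rate networks on a sequential
    pattern-matching working-memory task using a temporally restricted
    FORCE rule (recursive least squares confined to delay and response
    epochs, with readout feedback), and characterizes the emergent
    dynamics of the trained networks: fixed-point and limit-cycle
    detection by autonomous forward simulation, classification of the
    memory mechanism (direct fixed-point, indirect fixed-point,
    limit-cycle, mixed), Jacobian spectra at the origin and at task
    fixed points, connectivity structure of the rank-3 perturbation, and
    robustness assays under extended delays and distracting stimulus
    noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
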