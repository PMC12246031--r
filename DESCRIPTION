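Package: scarfem
Title: Biomorphoelastic Finite-Element Simulation of Post-Burn Scar
    Contraction and Hypertrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional moving-mesh finite-element simulator for
    post-burn dermal wound healing. Four coupled transport-reaction equations
    for fibroblasts, myofibroblasts, a generic signaling molecule and
    collagen are solved monolithically together with a visco-elastic momentum
    balance driven by myofibroblast traction and a morphoelastic evolution
    law for the effective Eulerian strain, on a Lagrangian triangulated mesh
    with quality-driven remeshing and an adaptive backward-Euler/Picard time
    integrator. Includes a one-at-a-time z-score parameter-sensitivity
    pipeline over hypertrophy and contraction outcome metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
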