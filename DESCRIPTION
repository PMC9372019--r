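Package: turingbc
Title: Turing Bifurcations of Reaction-Diffusion Systems Under Dirichlet and
    Neumann Boundary Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for two-species reaction-diffusion systems on a
    one-dimensional interval: linear Turing stability (dispersion relation,
    instability window, critical domain scale, kernel and adjoint-kernel
    vectors, patterning region in the (L, D_v) plane), weakly nonlinear
    multiple-scales amplitude equations whose generic form depends on the
    boundary conditions (transcritical under Dirichlet conditions pinned at
    the homogeneous steady state, pitchfork under zero-flux Neumann
    conditions), method-of-lines simulation on static and slowly growing
    domains, and pseudo-arclength continuation of discretized steady states
    with stability classification, fold and bifurcation detection and branch
    switching.  The Schnakenberg activator-inhibitor system is included as
    the canonical worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
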