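Package: coastdiff
Title: Growth-Diffusion Models of Coastal Urban Population Dynamics
Version: 1.0.0
Authors@R: person("Coastdiff", "Maintainers", email = "coastdiff@example.org",
    role = c("aut", "cre"))
Description: Closed-form and numerical solutions for a family of
    one-dimensional growth-diffusion models of a city spreading inland from
    a straight coastline: pure diffusion from a step boundary, exponential
    growth-diffusion under synchronized and density-regulated coastal
    boundary conditions (via Duhamel's principle), steady-state band waves
    with an entropy-maximizing band width, and the logistic growth-diffusion
    model with its stationary coastal front. A general Crank-Nicolson
    method-of-lines reaction-diffusion integrator cross-validates every
    closed form, and a command-line interface regenerates the standard
    scenario presets as delimited text.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, Matrix, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
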