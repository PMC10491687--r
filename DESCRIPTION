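Package: pwmalnut
Title: Piecewise Classical-Fractional-Stochastic Simulation of a
    Compartmental Malnutrition Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a four-compartment model of malnutrition among
    pregnant women and their children (susceptible females, malnourished
    boys, malnourished girls, underweight individuals) whose dynamical law
    changes regime over time: a classical ordinary-differential-equation
    phase, a fractional-memory phase under a choice of power-law (Caputo),
    exponential-decay (Caputo-Fabrizio) or Mittag-Leffler
    (Atangana-Baleanu-Caputo) kernel, and a stochastic phase with
    multiplicative white noise.  Provides the model's drift and diffusion
    fields, equilibria, the basic reproduction number with its
    next-generation-matrix cross-check, the noise-adjusted persistence
    threshold, three-step Adams-Bashforth integrators for every regime
    (including the Newton-polynomial fractional multistep schemes and a
    stochastic multistep), an Euler-Maruyama reference solver, seeded
    Brownian path and scenario generators, and ensemble, histogram,
    ergodicity and convergence diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
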