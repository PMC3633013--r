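Package: beauchemin
Title: Simulation and Analytical Toolkit for the Beauchemin Model of
    Lymphocyte Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Particle-based simulation of the Beauchemin model of stochastic
    lymphocyte migration (fixed-length straight runs in uniformly random 3-D
    directions separated by stationary turning pauses), together with the
    model's closed-form motility coefficient, single-particle and ensemble
    mean square displacement, squared confinement ratio, and the convection
    speeds of four biased-migration (taxis) modes. Includes estimators for
    track statistics with standard errors, least-squares parameter fitting
    (linear mean-square-displacement and Fuerth-equation fits), a simulation
    grid-ranking facility, CSV track import/export and a command-line
    interface, so that simulated tracks and closed forms cross-validate each
    other.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
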