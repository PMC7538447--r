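Package: cbmech
Title: Centre-Based Cell Mechanics with Interchangeable Force Laws
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and numerical analysis of centre-based (overlapping
    spheres) models of multicellular mechanics. Provides the pairwise
    cell-cell interaction force laws used by common tissue simulators
    (cubic, piecewise quadratic, generalized linear spring, plus linear and
    Hertz), overdamped equations of motion assembled over a cell population
    with a distance cutoff, fixed-step explicit integrators (forward Euler,
    midpoint, two-step Adams-Bashforth) next to a high-accuracy adaptive
    reference solver, an event-driven division scheduler, and the
    calibration and robustness toolbox that goes with them: relaxation-time
    parameter fitting, force-shape fitting, closed-form monotonicity and
    stability step-size bounds, and empirical convergence studies. Results
    are returned as tibbles with broom-style tidiers and ggplot2 autoplot
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
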