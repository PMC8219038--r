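Package: leafflux
Title: Leaf Gas-Exchange Simulation and Parameter Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward simulation and inference for leaf gas-exchange
    experiments. Implements the Farquhar-von Caemmerer-Berry (FvCB)
    photosynthesis model coupled to stomatal and mesophyll CO2 diffusion,
    Laisk slope-intercept estimation of the apparent photorespiratory
    compensation point (ci*) and day respiration (Rd), the variable-J
    mesophyll conductance method with the dCc/dA reliability filter,
    non-rectangular hyperbola light-response and A-cc curve fitting,
    minimum (cuticular) conductance from leaf drying curves, relative
    water content, chamber leak-flow correction, gravimetric whole-plant
    transpiration, and stopped-flow exponential decay kinetics for
    membrane CO2 permeability assays. Seeded synthetic-data generators
    with known ground truth make every estimator testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
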