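Package: photoalloc
Title: Nitrogen-Constrained Modeling of C3, C3-C4 and C4 Photosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mechanistic model of leaf photosynthesis in which a fixed budget of
    photosynthetic nitrogen is allocated between Rubisco, the C4-cycle enzymes
    (PEPC and PPDK), and the thylakoid electron-transport chains (linear and
    cyclic). The package couples the nitrogen-to-capacity stoichiometry with
    light- and enzyme-limited CO2 assimilation for C3, C3-C4 intermediate,
    C4-like and C4 plants (parameterized for the genus Flaveria), a peaked
    Arrhenius temperature response, and a multistart constrained optimizer that
    finds the nitrogen and energy allocation maximizing assimilation in a given
    environment. Analysis tools include the required nitrogen re-allocation
    statistic between two optimal allocations, scenario comparison with
    normalized squared residuals and rank/sign tests, environment-grid inference
    of best-fitting (ancestral) environments, simulated gas-exchange response
    curves, and a seeded generator of noisy synthetic measurements.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
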