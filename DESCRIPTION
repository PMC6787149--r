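Package: paosens
Title: Global Sensitivity Analysis of a PAO Metabolic Model for EBPR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Uncertainty characterization and variance-based global
    sensitivity analysis for a mechanistic metabolic model of phosphorus
    accumulating organisms (PAO) in enhanced biological phosphorus removal
    (EBPR).  Provides a literature-style uncertainty database for 39 model
    inputs, Saltelli cross-sampled Sobol quasi-random designs, simulation of
    one 5-hour anaerobic-aerobic cycle (10 components, 10 kinetic processes,
    acetate and propionate stoichiometry, Arrhenius temperature and pH
    dependencies, sequential maintenance), Monte Carlo propagation to
    cycle-mean outputs, and importance quantification via standardized
    regression coefficients and first- and total-order Sobol indices with
    bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    ggplot2,
    generics,
    parallel,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
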