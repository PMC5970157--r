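Package: patrisim
Title: Forward-Time Simulation of Patrilineal Group Competition and
    Y-Chromosome Haplogroup Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time grid simulator of intergroup competition among
    patrilineal versus non-patrilineal cultural groups and its effect on
    Y-chromosome haplogroup diversity, together with a modified
    Lotka-Volterra competition model in which two male subpopulations share
    a single logistic female resource. Provides per-generation summary
    statistics (distinct-group and distinct-haplogroup counts, Gini-Simpson
    diversities), ensemble aggregation with mean and dispersion bands, a
    parameter-sweep driver, configuration file handling, and a command-line
    front end for reproducible simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    broom,
    deSolve,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
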