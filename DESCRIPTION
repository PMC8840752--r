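Package: sfekin
Title: Response-Surface Optimization and Mass-Transfer Kinetics of
    Supercritical Fluid Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing and simulating supercritical-CO2 extraction
    of plant solutes. Fits first- and second-order response surfaces to
    two-level factorial and Box-Behnken designs, produces the full sequential
    and adjusted ANOVA decomposition including lack-of-fit and pure error, and
    maximizes a fitted quadratic surface exactly over the experimental box by
    face enumeration. Implements three forward models for cumulative
    extraction-yield curves (Crank's analytic sphere-diffusion series,
    Sovova's three-period broken-and-intact-cells model, and Reverchon's
    plug-flow internal-diffusion model solved by the method of lines) together
    with least-squares parameter estimation by multi-start Nelder-Mead, the
    conversions between fitted and physical mass-transfer coefficients, and a
    deterministic synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
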