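Package: drykin
Title: Thin-Layer Convective Drying Kinetics, Transport Properties and
    Energy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for thin-layer convective drying of plant
    tissue (plantain banana slices). Converts raw time-weight series into
    dry-basis moisture content, moisture ratio and drying rate; fits seven
    semi-empirical thin-layer drying models (Newton/Lewis, Page, modified
    Page, Henderson-Pabis, logarithmic, Verma, diffusion approach) by
    bounded multi-start nonlinear least squares and ranks them by R-squared,
    reduced chi-squared and RMSE; estimates effective moisture diffusivity
    from the Fick slab solution, Arrhenius activation energy, and the
    Dincer-number to Biot-number to mass-transfer-coefficient chain;
    computes process energy consumption from dryer geometry and dry-air
    properties; and explores compound correlation among drying conditions
    through PCA and Ward hierarchical clustering. A seeded synthetic-run
    generator reproduces the study's measurement schedule and moisture
    range so every stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    mclust,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
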