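Package: avisim
Title: Mechanistic Simulation of the Global Seasonal Distribution of Birds
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Assembles a virtual global avifauna of resident and migratory
    bird species on an equal-area hexagonal world grid. Virtual species are
    pairs of contiguous seasonal range options grown by a climate-constrained
    spreading-dye process; each added species maximises energetic fitness,
    the balance between energy assimilated from net primary productivity and
    the costs of basal maintenance and migration derived from flight
    allometry. Includes a synthetic-planet generator, diversity-pattern and
    migration metrics, calibration scans over model parameters, and
    multi-time-slice runners for paleoclimate scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    geosphere,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
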