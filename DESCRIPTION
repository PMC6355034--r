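Package: casakit
Title: Computer-Assisted Sperm Analysis: Tracking, Kinematics,
    Directionality and Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, scriptable computer-assisted sperm analysis (CASA)
    toolkit. Detects and tracks motile cells in microscopy frame stacks,
    computes the full set of classical kinematic parameters (VCL, VSL, VAP,
    LIN, WOB, STR, ALH, BCF, MAD, DNC and Katz fractal dimension), tests
    directional bias of a track population (chemotaxis, thermotaxis or
    rheotaxis) with a bootstrap odds-ratio procedure, measures sperm-head
    morphometry (Feret calipers) on stained stills, counts membrane-intact
    versus damaged cells in dual-stained fluorescence images, and simulates
    chemoattracted populations with a persistent random walk model so the
    whole pipeline can be validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    EBImage,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
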