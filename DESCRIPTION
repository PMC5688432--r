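Package: famplanr
Title: Proximate-Determinants Fertility Modelling and Family-Planning
    Scenario Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Bongaarts proximate-determinants framework for
    fertility: indices for marriage, postpartum insusceptibility, induced
    abortion, sterility, and contraception combine with total fecundity to
    give the total fertility rate. Extends the framework to account for
    pregnancies and their outcomes (live births, induced abortions,
    miscarriages, stillbirths) with an intended/unintended breakdown, and
    projects multi-year scenarios of contraceptive scale-up with a
    lagged-TFR abortion index and constant calibrated total fecundity.
    Bundles method failure rates and reproductive-indicator presets for
    four illustrative countries, a YAML configuration interface, CSV report
    writers, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
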