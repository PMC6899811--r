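Package: mpabias
Title: Quantifying Placement Bias of Marine Protected Areas Relative to
    Abatable Threats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for asking whether marine protected areas
    (MPAs) are established where the threats they can abate actually occur.
    Classifies threat layers as stoppable or unstoppable, computes zonal mean
    stoppable threat for country and global marine ecoregions, accounts for
    protected area by IUCN category group with Monte Carlo imputation of
    missing establishment years, classifies ecoregions into protection-by-
    threat quartile sectors and risk categories with chi-square tests, and
    evaluates a country-level impact metric against a random-allocation
    counterfactual null. Ships a synthetic world generator with tunable
    placement bias so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
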