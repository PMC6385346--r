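Package: greenec
Title: Emergent Constraints on Northern High-Latitude GPP from Greening Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for constraining multi-model projections of gross primary
    production (GPP) in the northern high latitudes (60-90 N) with the observed
    sensitivity of annual maximum leaf area index to a combined CO2/warming
    driver. Builds the proxy driver as the first principal component of annual
    atmospheric CO2 and growing degree days above 0 C, estimates greening
    sensitivity with a prescribed linear error model, fits the cross-ensemble
    emergent relationship with bootstrap confidence contours, and combines it
    with the observation PDF to obtain a constrained projection PDF. Includes
    atmospheric CO2 seasonal-cycle diagnostics (detrended seasonal cycles and
    the summertime drawdown-slope change statistic), GPP-to-NPP scaling, a
    Mann-Kendall greening/browning trend classifier, and synthetic-data
    generators with known ground truth for end-to-end validation.
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
    ncdf4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
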