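Package: sitenet
Title: Monitoring-Network Site Selection for Urban Air Pollution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs supplementary air-pollution monitoring networks for
    epidemiological studies. From hourly pollutant measurements at existing
    regulatory monitors and geographic covariates at monitor, residence and
    candidate locations, the package screens annual averages under
    completeness criteria, fits a land-use regression by constrained forward
    selection with multicollinearity guards and leave-one-out cross-validation,
    partitions all locations by multi-restart k-means on the scaled selected
    covariates with a decrease-in-overall-deviation (DiD) criterion for the
    number of clusters, and allocates a fixed number of new monitoring sites
    to the clusters where residences are under-represented by existing
    monitors. A synthetic-city generator with known covariate effects supports
    validation, and clustering robustness is assessed by adjusted Rand indices
    over subsample reruns.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
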