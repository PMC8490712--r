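Package: gemyield
Title: Genetics x Environment x Management Decomposition of County Crop Yield
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits a multiplicative decomposition of county-year maize yield into
    genetics, environment, and management components. The environment component
    is a weekly growth potential built from quadratic interactions of weather
    and soil variables with separate coefficients for the vegetative and
    reproductive stages; genetics is a district-level polynomial trend in year;
    management combines plant density with planting and harvesting progress.
    Calibration alternates two convex quadratic programs on random subsamples
    with blended, cross-validated incumbent updates. Includes leave-one-year-out
    and leave-one-county-out evaluation, nearest-year and nearest-county
    baselines, in-season forecasting by splicing observed and historical
    weather, and a synthetic panel generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
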