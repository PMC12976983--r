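Package: ecenest
Title: Extreme Climatic Event Exposure and Nestling Fitness Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how extreme climatic events (ECEs) during
    nestling development affect fledging mass and local recruitment in
    cavity-nesting birds. Calibrates percentile-tail ECE thresholds from
    daily temperature and rainfall deviations relative to monthly baselines,
    quantifies per-brood exposure over developmental stage windows, and fits
    linear and generalised linear mixed models with crossed random intercepts,
    natural cubic spline terms, interaction terms and a path-analysis
    decomposition of lay-date effects. Includes a stochastic weather and
    breeding-data generator with known truth so the full pipeline can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
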