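Package: bloomwarn
Title: Early Warning of Cyanobacterial Blooms from Chlorophyll Fluorescence
    Lead Times
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pipeline for forecasting Microcystis-dominated cyanobacterial
    blooms in lake monitoring programmes from PAM-fluorometry quantum yields.
    Fits trigonometric (harmonic) seasonal regressions to monthly
    chlorophyll-fluorescence parameters and algal cell densities, estimates
    the lead/lag between the fitted seasonal curves by cross-correlation on a
    daily grid, screens environmental drivers with site-random-intercept
    mixed models, and applies a threshold-plus-trend decision rule that
    forecasts bloom likelihood and density peaks roughly forty days ahead.
    Includes a synthetic multi-site generator emulating the monthly
    lake-monitoring design so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'config.R'
    'field.R'
    'seasonal.R'
    'records.R'
    'glmm.R'
    'lag.R'
    'synthetic.R'
    'warning.R'
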