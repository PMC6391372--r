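Package: sowshift
Title: Weather-Window Constraints on Soybean Yield and Optimal Sowing-Date Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline for identifying month-specific weather
    constraints on rainfed soybean yield and estimating state-specific
    optimal sowing-date shifts, their yield effects, monetary effects, and
    spring frost risk. Daily weather is reduced to sowing-relative 30-day
    window features (cumulative precipitation and solar radiation, mean
    vapor pressure deficit, maximum temperature, and relative humidity);
    a conditional-inference regression tree with permutation tests locates
    the yield-limiting windows; a component-wise functional gradient
    descent (L2 boosting) model predicts state-year yield from weather,
    coordinates, and year; counterfactual sowing-date scenarios are built
    by re-anchoring the feature windows over fixed observed weather; a
    hierarchical quadratic response model extracts per-state optimal
    shifts; and downstream modules convert yield changes into
    inflation-adjusted monetary effects and screen candidate shifts
    against frost-probability climatologies. A synthetic-data generator
    with recorded ground truth drives the recovery test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
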