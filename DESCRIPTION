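Package: biohackr
Title: Digital Biohacking of Food Diaries with a Personalized Metabolic Avatar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating minimal dietary interventions
    ("digital biohacking") on per-participant food diaries. For each meal the
    highest-calorie non-condiment item is replaced by a same-category
    alternative that cuts 100-200 kcal without raising the meal's carbon
    footprint. A personalized metabolic avatar -- a small gated recurrent unit
    forecaster of daily weight change driven by energy balance and
    macronutrient composition, with a closed-form linear backend -- simulates
    weight trajectories under the actual and the biohacked diet via
    walk-forward validation and simulation. An evaluation layer provides the
    paired t-test and linear-regression protocol for comparing simulated
    against observed two-week weight changes, and a synthetic-diary generator
    produces energy-balance-consistent cohorts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
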