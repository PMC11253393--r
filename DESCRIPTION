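Package: fireopioid
Title: Monte Carlo Model of Wildfire-Attributable Opioid Misuse via Anxiety
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic portrayal of the pathway from wildfire exposure to
    opioid misuse among U.S. young adults, mediated by increased anxiety
    incidence and severity. Provides the deterministic epidemiologic algebra
    (odds/probability conversion, odds- and risk-ratio application, scenario
    mixture prevalences), calibration of the no-anxiety misuse probability to
    a target baseline prevalence, a seeded 50,000-iteration Monte Carlo
    uncertainty propagation with percentile uncertainty intervals, a
    risk-ratio sensitivity sweep, and an individual-level synthetic cohort
    generator used as a brute-force oracle and for parameter-recovery
    experiments. All user-facing functions return tibbles; fitted simulation
    objects support tidy(), glance() and autoplot().
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
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
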