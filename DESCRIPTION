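Package: cpaudit
Title: Conditional Power Auditing of Randomised Trials Stopped for Futility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes conditional power at an interim analysis of a
    randomised trial on the information-time (Brownian score) scale, under
    the current-trend, original-design, interim-confidence-limit and null
    hypotheses about future data. Converts published trial summaries
    (per-arm counts, means, survival summaries, p-values) into interim
    statistics, audits registries of trials stopped early for futility
    (computed, reported-only or insufficient-information verdicts; binned
    conditional-power distributions stratified by sponsor), generates
    synthetic trial registries emulating surveyed stopping practice, and
    simulates group-sequential trials to quantify the estimation bias
    induced by futility stopping rules.
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
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
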