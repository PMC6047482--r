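Package: bwsrank
Title: Best-Worst Scaling Analysis of Blocked Outcome-Prioritization Surveys
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipelines", email = "pipelines@example.org",
           role = c("aut", "cre"))
Description: Tools for designing, simulating, and analyzing stated-preference
    surveys in which respondents rank patient-centered outcomes. Constructs
    near-balanced incomplete block designs that split a large harm catalog
    into small ranking sets, simulates respondents under a Plackett-Luce
    latent-utility model with configurable demographics and item
    nonresponse, applies an eligibility-filter cascade with participant-flow
    accounting, summarizes benefit rankings by median and interquartile
    range, scores harms by best-worst scaling (the difference between the
    proportion of respondents ranking an item most and least important),
    and quantifies rank-order recovery against known simulated preferences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
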