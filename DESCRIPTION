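Package: ptegarden
Title: Contamination and Dietary Health-Risk Screening for Urban Garden Produce
Version: 0.1.0
Authors@R: person("Garden", "Risk Tools", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for screening potentially toxic elements (PTEs) in urban
    garden soils and vegetables. Covers left-censored (below detection limit)
    concentration handling, contamination factors with Hakanson classes and
    the pollution load index, soil-to-plant transfer factors, estimated
    daily intake, hazard quotients and hazard index, carcinogenic risk for
    arsenic, regulatory trigger-value and EU food-limit screening, two-stage
    group-comparison statistics with compact letter displays, and a
    log-normal synthetic data generator for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
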