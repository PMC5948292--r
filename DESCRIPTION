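Package: shisim
Title: Adverse-Selection Dynamics in Voluntary Supplementary Health Insurance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Microsimulation of the adverse-selection (death) spiral in a
    voluntary supplementary health insurance market and of the capacity of
    premium differentiation to counteract it. Generates seeded synthetic
    insured panels with zero-inflated, heavy-tailed annual claims and
    year-to-year persistence; predicts individual claims with a gamma
    generalized linear model (log link) on prior-year information; sets
    premiums as prior-year pool mean claims plus a proportional loading under
    community rating, 28 age-gender classes, 140 age-gender-quintile classes,
    or full individual risk rating; classifies the financial profitability of
    holding the policy using a Pratt risk premium; and simulates 25 years of
    opt-out/opt-in market dynamics with data looping, reporting uptake,
    premium and pool-claims trajectories across Monte-Carlo replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
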