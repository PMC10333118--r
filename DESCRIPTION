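Package: forestsynth
Title: Synthetic-Control Evaluation of Avoided Deforestation and Carbon
    Co-Benefits in Protected Areas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the impact of protected-area policy
    interventions on forest loss using the synthetic control method.
    Builds counterfactual cumulative forest-loss trajectories for treated
    reserves from weighted combinations of untreated donor reserves,
    performs placebo-based permutation inference on post/pre MSPE ratios,
    runs anticipation and donor-trimming robustness checks, and converts
    averted forest loss into avoided CO2-equivalent emissions valued at
    the social cost of carbon and at voluntary carbon-market prices.
    Includes a synthetic panel generator with known ground truth so the
    whole pipeline is testable without geospatial inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
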