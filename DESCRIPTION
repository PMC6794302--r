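Package: trajmine
Title: Mining Temporal Disease Trajectories from Longitudinal Inpatient Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering temporal disease associations in
    longitudinal inpatient admission registries and assembling them into
    disease-trajectory graphs. Implements the relative-association (RA)
    comorbidity statistic with a one-sided binomial test and
    Benjamini-Hochberg false-discovery-rate control, a sign-test based
    temporal-directionality score for ordering diagnosis pairs, and a
    greedy algorithm that concatenates significant directed pairs into
    directed acyclic graphs of disease progression terminating in
    in-hospital death. Includes a synthetic multi-edition registry
    generator with planted disease-pair effects so the full pipeline can
    be exercised and validated without access-restricted patient data,
    plus cohort validation statistics (relative risk, hypergeometric
    enrichment, rate and fold reporting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
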