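Package: acfmnet
Title: Asynchronous-Correlation Fluctuation-Mode Networks for Paired Weekly Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Transforms a pair of weekly time series (a continuous economic
    index and a nonnegative event-count series) into lag-scenario-specific
    directed weighted fluctuation-mode transition networks. Provides lagged
    sliding-window Pearson correlation scanning, five-level symbolization of
    correlation coefficients, coarse-graining of symbols into fixed-length
    fluctuation modes, construction of mode-transition networks, and the
    associated network-topological statistics: node strength, transmission
    probabilities, log-log power-law fits of the weighted-degree distribution,
    k-plex cohesive-subgroup mining with clustering-coefficient core modes,
    Burt constraint and Coleman-Theil structural-hole hierarchy, and
    shortest-path statistics. A periodogram module detects periodicity in the
    correlation sequences, and a seeded synthetic-data generator produces
    index/count pairs with known lagged coupling and periodicity so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
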