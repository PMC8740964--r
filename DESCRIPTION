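Package: cogcascade
Title: Cognitive Cascades of Belief on Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates public opinion diffusion (POD): institutional
    broadcaster agents inject belief-valued messages into random social
    networks (Erdos-Renyi, Watts-Strogatz, Barabasi-Albert, multiplicative
    attribute graphs) whose agents update a discrete belief under simple,
    proportional-threshold, or cognitive contagion rules, including the
    defensive cognitive contagion (DCC) sigmoid that combines dissonance
    and exposure effects. Provides the accompanying analysis apparatus:
    adoption-probability matrices, graph homophily scores, cascade path
    probabilities, qualifying-path censuses over graph ensembles, and
    cross-topology correlation of belief timeseries.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
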