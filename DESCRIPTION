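Package: morrarand
Title: Randomness Indices and Simulation for Morra Hand-Number Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying random number generation under concurrent
    game load in the traditional hand game Morra. Provides the game engine
    (play validity rules, round adjudication, the 25x25 payoff matrix, and
    team-match simulation), five randomness indices for bounded-alphabet
    response sequences (redundancy, frequency of paired responses, null-score
    quotient, coupon score, and repetition-gap mean), the Spearman footrule
    rank-distance memory score, first-order Markov agents that emulate
    favourite-number bias, perseveration and dual-task load, and a
    descriptive 2x2 comparison report with kernel-density overlap effect
    sizes and permutation contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
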