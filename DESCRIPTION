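Package: explorexploit
Title: Explore/Exploit State Analysis for Trial-Aligned Spike Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing explore/exploit state coding in trial-aligned
    single-unit recordings from a serial object-search task. Provides a data
    model of the task (problems of four trial cycles, one or two rewarded
    targets among four objects), analytic chance expectations for random
    search, a behavioural and Poisson-spiking simulator with ground-truth
    labels, cross-validated selection of explore- and exploit-preferring
    cells by factorial ANOVA, normalised peristimulus time histograms,
    one-shot learning and reward-expectancy analyses, temporal
    cross-generalization of cycle preference, and a population
    mean-difference discriminant with permutation inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    car,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
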