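Package: adodisc
Title: Adaptive Design Optimization for Delay Discounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Bayesian adaptive design optimization (ADO) for measuring delay
    discounting. Implements the hyperbolic discounting model with a softmax
    choice rule, grid-based sequential posterior inference over the discounting
    rate and inverse temperature, and mutual-information-optimal selection of
    each trial's choice stimulus. Includes the conventional adjusting-amount
    staircase procedure as a comparator, synthetic softmax-hyperbolic agents
    for simulation studies, and evaluation metrics for test-retest reliability
    (Lin's concordance correlation coefficient computed cumulatively per
    trial), precision (posterior standard deviation of the log discounting
    rate), and efficiency (trials required to reach a reliability threshold).
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
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
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
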