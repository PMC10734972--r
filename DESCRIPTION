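Package: nmadesign
Title: Power and Sample Size for a Two-Arm Trial Planned Jointly with a
    Network Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans a new two-arm binary-outcome trial whose result will be
    combined with an existing network meta-analysis (NMA). Fits the
    fixed-effect contrast-based NMA by weighted least squares, extracts the
    indirect standard error for any treatment pair, computes the power of
    the new trial when analysed alone or jointly with the network, and
    solves the two design problems: the allocation of a fixed total sample
    size that maximises power, and the minimum total sample size (even or
    uneven allocation) that reaches a target power. Includes Monte-Carlo
    simulation protocols that validate the closed-form power against
    simulated trials on synthetic networks, and a command-line interface.
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
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
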