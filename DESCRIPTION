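Package: pndecay
Title: Sample-Size-Aware Significance Analysis via the Exponential Decay
    of p-Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats the p-value of a two-sample test as a function p(n) of
    the subsample size n rather than as a single number.  Monte Carlo
    cross-validation subsampling draws many subsample pairs at a grid of
    sizes, the resulting p-value cloud is fitted with the exponential model
    p(n) = a * exp(-c * n), and the fitted amplitude and decay rate are
    turned into quantitative decision parameters: the convergence point
    n_gamma, the area distance delta between p(n) and the significance
    level alpha, a binary decision index theta separating practically
    meaningful differences from sample-size artifacts, and the minimum
    sample sizes n_alpha (fitted) and n_alpha_hat (empirical) at which
    significance is reached.  Includes a synthetic normal-distribution
    study for validation, a reliability (robustness-rate) protocol,
    long-format CSV/TSV input, JSON/CSV reports, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
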