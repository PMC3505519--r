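Package: jzscor
Title: Default Bayesian Hypothesis Tests for Correlation and Partial
    Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Jeffreys-Zellner-Siow (JZS) Bayes factor tests for the presence
    of a Pearson correlation and of a partial correlation, implemented as
    nested linear-model comparisons under a mixture-of-g prior, alongside the
    classical t tests. Includes verbal evidence categories and posterior model
    probabilities, sequential Bayes-factor monitoring over accumulating
    observations, a fixed-g Zellner Bayes factor that demonstrates the
    Jeffreys-Lindley-Bartlett paradox, a multivariate-normal synthetic-data
    generator with optional exact empirical correlations, and a command-line
    interface over delimited text files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    withr
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
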