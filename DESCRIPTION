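Package: locmix
Title: Mixture Models for Spatial Working-Memory Recall Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes errors in two-dimensional spatial working-memory
    tasks into imprecision, misbinding (swap errors) and guessing using
    bivariate-Gaussian mixture models, with the classic one-dimensional
    von Mises mixture as a reference implementation. Provides maximum
    likelihood and MCMC fitting, response-bias corrections (constant,
    edge-proportional and radial), kernel-density "response sampling"
    guess distributions with cross-validated comparison, change-detection
    (2AFC) likelihoods obtained by integrating the continuous error
    density, distance-based behavioural metrics with chance-corrected
    swap errors and split-half reliability, and a simulation harness for
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
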