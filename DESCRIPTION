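Package: numchan
Title: Numerosity-Tuned Sensorimotor Channels from Individual Differences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterises numerosity-tuned sensorimotor channels
    from inter-individual covariance of reproduction precision. Provides a
    generative channel/observer simulator for number-matching (tapping) tasks,
    a Weber-fraction preprocessing pipeline with z-score outlier removal,
    inter-participant correlation matrices and their dependence on numerical
    distance (with permutation nulls), simulation-based fitting of 1/2/4-channel
    models by R-squared grid search, hierarchical clustering with an
    inconsistency-based cut and contiguity controls, factor/principal-component
    extraction with promax rotation and log-Gaussian tuning fits, and the
    duration-matching control analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
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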