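Package: hwks
Title: Fast Change-Point Detection with Haar Wavelet Trees and a
    Modified Kolmogorov-Smirnov Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Locates an abrupt distributional change in a univariate time
    series in O(log n) statistic evaluations by descending a pair of binary
    Haar coefficient trees (approximation and detail) under a scaled
    two-sample Kolmogorov-Smirnov node statistic. Includes three classical
    baseline detectors (exhaustive Kolmogorov-Smirnov split scan, one-level
    Haar detail maximum, Welch t split scan), a seeded synthetic-data
    generator for mean-shift and ECG-like regime-switch series, a
    Monte-Carlo benchmark harness reporting error, accuracy and hit rate
    per method and design cell, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
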