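Package: popdecode
Title: Neural Population Decoding with Pseudo-Populations and Temporal
    Cross-Decoding
Version: 0.1.0
Authors@R:
    person("popdecode", "maintainers", email = "maintainers@popdecode.org",
           role = c("aut", "cre"))
Description: A modular framework for neural population decoding. Reads
    per-site spike-train tables in a raster format, bins them into
    firing-rate tables, assembles pseudo-population training and test
    sets with k-fold cross-validation over repeated resample runs,
    classifies with a maximum correlation coefficient or Poisson naive
    Bayes classifier after optional z-score normalization and ANOVA
    feature selection, and summarizes performance as zero-one loss,
    normalized rank and decision-value time courses, temporal
    cross-decoding matrices and confusion matrices. Includes a
    generalization datasource for training and testing on different,
    index-paired label levels, a managed results log with a parameter
    manifest, a synthetic tuned-neuron raster generator for fully
    offline testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    parallel,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
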