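Package: visens
Title: Ensemble Visual Encoding Models for Novel Individuals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates region-level visual encoding models that
    predict a novel subject's brain responses to stimuli as a linear
    combination, fitted by ordinary least squares, of reference subjects'
    pretrained encoding-model predictions. Provides per-subject linear
    readout models on precomputed stimulus features with random or
    group-average initialization and early stopping, leave-one-out linear
    and average ensembles, evaluation via prediction accuracy,
    inter-subject correlation (ISC), prediction consistency with
    permutation inference, across- and within-subject noise ceilings, and
    model-comparison statistics (Wilcoxon signed-rank, Friedman with
    Benjamini-Hochberg correction). A synthetic multi-subject cohort
    generator with shared and idiosyncratic signal components makes the
    whole pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
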