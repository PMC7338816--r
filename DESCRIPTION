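Package: rnsmetrics
Title: History-Weighted Evaluation of Closed-Loop Neurostimulator Device Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative evaluation of responsive neurostimulator (RNS-type)
    detector and stimulation behaviour per programming epoch. Classifies manually
    annotated electrocorticography (ECoG) snippets into confusion-matrix outcomes,
    extrapolates detector accuracy, sensitivity, specificity and latency by
    weighting per-stratum snippet statistics with aggregate device histogram
    counts, computes stimulation-dose and event-rate metrics, and quantifies the
    bias of snippet-only estimates with Bland-Altman and signed-rank agreement
    statistics. Includes a seedable device simulator that reproduces the device's
    storage constraints (4-slot ECoG storage with trigger-type slot reservation,
    event-list truncation, hourly histogram saturation) so that estimates can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
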