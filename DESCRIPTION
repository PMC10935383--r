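Package: wearmiss
Title: Missing-Data Statistics and Mechanism Classification for Wearable
    Sensor Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise missing data in wearable-sensor time
    series (continuous glucose monitoring, heart rate and step counts) and
    to classify the missing-data mechanism as MCAR, MAR or MNAR. Implements
    modality-specific missingness definitions and wear-time rules, pooled
    gap-size frequency tables with maximum-likelihood fitting of discrete
    distributions (Planck, geometric, Zipf and others) and goodness-of-fit
    testing, per-subject missing-data dispersion over time groupings with
    Kruskal-Wallis and Dunn post hoc analysis, and a two-step decision rule
    combining both. Includes a synthetic cohort generator with mechanistic
    missingness injectors (device storage-buffer overflow with
    synchronisation events, iid dropout, time-dependent dropout,
    heavy-tailed gap processes) so every stage can be validated against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
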