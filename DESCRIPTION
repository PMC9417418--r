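Package: sleepod
Title: Sleep EEG Correlates of Ocular-Dominance Homeostatic Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking NREM sleep electrophysiology to visual
    homeostatic plasticity induced by short-term monocular deprivation.
    Computes the deprivation index from binocular-rivalry percept timelines,
    detects and characterizes sleep slow oscillations (zero-crossing and
    amplitude criteria with multi-channel event clustering) and sleep
    spindles (sigma-band envelope-distance signal with per-period adaptive
    thresholds), estimates band power and sleep-macrostructure parameters,
    and runs region-of-interest change-score statistics (Spearman
    correlations with Benjamini-Hochberg FDR control, Wilcoxon signed-rank,
    one-sample and paired t-tests, repeated-measures ANOVA). A seeded
    synthetic-data module generates ground-truthed EEG with embedded slow
    oscillations and spindle packets, gamma-distributed rivalry timelines,
    and rank-correlated subject cohorts so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    IRanges,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
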