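Package: afburden
Title: Atrial Fibrillation Burden Quantification from Minute-Epoch Rhythm Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying atrial fibrillation (AF) burden from
    minute-resolution rhythm timelines such as those produced by wrist-worn
    photoplethysmography (PPG) monitors, and for validating a device stream
    against a gold-standard (Holter ECG) annotation. Implements minute-level
    AF labeling from per-minute AF-beat fractions, episode extraction, five
    burden metric families (duration ratios, episode-frequency ratios, AF
    density, circadian variability statistics including average real
    variability and variation of the mean, and rapid-ventricular-rate
    proportions), epoch-level diagnostic accuracy with Wilson score intervals,
    ROC threshold sweeps, and per-metric concordance statistics (mean absolute
    error, Spearman rank correlation, Mann-Whitney U). A transparent
    inter-beat-irregularity classifier with minute-level fusion stands in for
    proprietary detectors, and a semi-Markov synthetic cohort generator with a
    circadian-modulated AF process and an imperfect observation channel
    exercises the full pipeline without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
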