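Package: dotprobe
Title: Individualized Dot-Probe Attention Training Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for individualized attention-bias-modification studies
    built on the modified dot-probe task: nonmetric multidimensional
    scaling of stimulus similarity ratings by stress majorization
    (SMACOF), training-session planning with contingent probe placement,
    headless session execution with JSON-lines trial logging,
    reaction-time preprocessing (correct-only filtering and
    per-participant outlier trimming), screening-instrument scoring
    (PHQ-9, PCL-C, anxiety and adherence scales), pre/post outcome
    statistics (paired t, Cohen's d, chi-square, phi coefficient), and a
    synthetic-cohort simulator for end-to-end pipeline validation and
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    optparse
Config/testthat/edition: 3
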