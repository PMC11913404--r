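Package: routinometry
Title: Routine Formation and Peri-Event Calcium Dynamics in Operant Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking operant reward-seeking behavior to
    fiber-photometry calcium dynamics. Segments timestamped action events
    (nose-pokes, magazine entries and exits) into behavioral blocks and
    reward-to-reward cycles, computes a per-cycle routine index with
    principled selection of its normalizing transformation, converts raw
    fluorescence to smoothed z-scored dF/F against a sliding minimum-of-mean
    baseline, aligns activity around behavioral events, and tests for
    routine-related neural modulation with per-timepoint regression,
    cluster-based permutation inference, likelihood-ratio comparison of
    nested mixed models, and shuffle-null validations. Includes a synthetic
    cohort generator with known ground truth so every stage is testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
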