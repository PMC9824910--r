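Package: glandmark
Title: Generalized Landmark Analysis for Dynamic Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic prediction of a terminal clinical event from longitudinal
    cohort data via generalized landmark analysis (GLA). Visit-level records
    are stacked into a landmark dataset of residual survival times, and a
    weighted Cox proportional hazards model is fitted locally around the
    query subject's current value of one or two landmark variables (for
    example a biomarker such as eGFR, or time on study, which recovers
    classical landmark analysis). Kernel weights with a span-based adaptive
    bandwidth implement the localization; horizon-specific event
    probabilities come from a weighted Breslow baseline hazard. The package
    also provides the static prediction model baseline, censoring-adjusted
    accuracy measures (time-dependent AUC and Brier score with inverse
    probability of censoring weighting), a half-split cross-validation
    protocol with subject-level bootstrap intervals, span selection by
    cross-validated accuracy, and a longitudinal-survival cohort simulator
    with controllable coefficient drift.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
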