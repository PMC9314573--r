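Package: rqasync
Title: Multilevel Physiological Synchrony from Multidimensional Recurrence
    Quantification Analysis
Version: 0.1.0
Authors@R:
    person("Physiological Synchrony", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Quantifies physiological synchrony in triads from cardiac
    interbeat-interval (IBI) series using multidimensional recurrence
    quantification analysis (MdRQA). Provides phase-space delay embedding,
    recurrence plots and vertical-line recurrence measures (%REC, %LAM, meanV,
    maxV), embedding-parameter estimation (average mutual information, false
    nearest neighbors, recurrence-rate radius calibration), group-level and
    individual-level (dyad-averaged) synchrony scores, a z-composite Vertical
    Synchrony measure and its task-minus-baseline change (delta synchrony),
    false-pair surrogate testing with exact Wilcoxon signed-rank contrasts, and
    linear mixed-effects models predicting group cohesion from delta synchrony.
    Includes a synthetic-data generator with tunable within-group coupling and
    known cohesion effect sizes so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
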