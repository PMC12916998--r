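Package: pcsdm
Title: Parallel Constraint Satisfaction Decision Modeling and
    Multiple-Measure Strategy Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modeling probabilistic inference decisions with a
    Parallel Constraint Satisfaction (PCS) network and classical decision
    heuristics (take-the-best, equal weights, chance-corrected weighted
    additive). Derives per-task predictions for choices, decision times,
    and confidence; classifies individual participants to strategies by
    multiple-measure maximum likelihood (MM-ML) with BIC model selection,
    grid-search parameter fitting, saturated-model misfit checks, and
    k-fold cross-validation; simulates complete studies with known
    ground-truth strategies; and reproduces a full analysis pipeline
    (exclusions, ln-time preprocessing, adherence, Fisher-z averaged
    prediction-behavior correlations, rational-benchmark performance, and
    condition comparisons).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
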