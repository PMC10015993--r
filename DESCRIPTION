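Package: causalworlds
Title: Counterfactual Causal-Strength Measures over Ensembles of Simulated
    Election Worlds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes actual-causation strength measures over Monte-Carlo
    ensembles of possible election outcomes. Implements the counterfactual
    effect size model (CESM), the necessity-sufficiency model, distance from
    pivotality, observational and interventional Delta-P (the latter equal to
    the probability of necessity and sufficiency), and Cheng's causal power,
    each mapping a voting unit to a causal-strength score for the focal
    candidate's overall victory. Includes readers for forecast simulation
    files and human ratings tables, a synthetic-data module that generates
    forecast-like ensembles (latent-margin probit with a shared national
    shock) and Likert-style ratings from a chosen generating model, and the
    model-comparison statistics used to evaluate the measures against human
    causal judgments: state-mean correlations, per-participant correlations,
    paired permutation tests between competing models, partial regressions
    controlling for prior probability and electoral votes, and subgroup
    invariance checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
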