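Package: survite
Title: Counterfactual Treatment Recommendation for Survival Data
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Individual treatment effect (ITE) estimation and treatment
    recommendation for right-censored survival outcomes, built around a
    glioblastoma radiotherapy-versus-chemoradiotherapy use case. Provides a
    synthetic SEER-like cohort generator with known ground-truth effects,
    per-arm T-learner survival models (Cox proportional hazards, log-rank
    survival trees, random survival forests, and a Cox-loss neural network),
    a balanced twin-head survival network that aligns the two arms' latent
    representations with an integral probability metric penalty, and an
    evaluation battery: hazard ratios, IPTW-adjusted hazard ratios,
    restricted-mean-survival-time differences, number needed to treat,
    concordance and integrated Brier scores, and time-dependent Shapley
    attributions of predicted survival functions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
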