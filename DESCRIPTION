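Package: rrmsce
Title: Markov Cohort Cost-Effectiveness Model of Treatment Escalation in
    Relapsing-Remitting Multiple Sclerosis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Lifetime Markov cohort state-transition model comparing early
    escalation to natalizumab against switching among immunomodulators with
    late escalation in relapsing-remitting multiple sclerosis, from the
    Italian societal perspective. Provides parameter loading and validation
    from a plain-text configuration, estimation of annual EDSS-shift
    distributions from longitudinal patient records, the cohort transition
    engine, discounted cost and QALY accounting with incremental
    cost-effectiveness comparison, deterministic and probabilistic
    sensitivity analyses with cost-effectiveness acceptability curves, and a
    synthetic-data module generating placeholder values for unpublished
    model inputs and simulated EDSS trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
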