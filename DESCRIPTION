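Package: nsclcCEA
Title: Markov Cohort Cost-Effectiveness Modelling of First-Line Immunotherapy
    for Advanced Nonsquamous NSCLC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time Markov cohort model for the cost-effectiveness of
    first-line camrelizumab plus pemetrexed-carboplatin (CPC) against
    pemetrexed-carboplatin chemotherapy (PC) and, indirectly, against
    pembrolizumab plus pemetrexed-platinum (PPP) in advanced nonsquamous
    non-small-cell lung cancer from the Chinese healthcare-system perspective.
    Provides log-logistic and Weibull survival extrapolation with
    hazard-ratio adjustment, Kaplan-Meier pseudo-individual-patient-data
    reconstruction with maximum-likelihood refitting, strategy costing with
    treatment-duration caps and patient-assistance rules, a four-state cohort
    engine with an individual-level microsimulation oracle, one-way
    deterministic sensitivity analysis, threshold search, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves,
    Bucher anchored indirect comparison, and a synthetic-data module so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    jsonlite
Config/testthat/edition: 3
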