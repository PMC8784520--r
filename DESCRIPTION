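Package: psmcea
Title: Partitioned-Survival Cost-Effectiveness Modelling for First-Line
    NSCLC Immunotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort cost-effectiveness pipeline for comparing first-line
    pembrolizumab plus chemotherapy against pembrolizumab monotherapy in
    metastatic non-small-cell lung cancer with high PD-L1 expression.
    Implements log-logistic survival extrapolation with hazard-ratio
    adjustment, registry-spliced and background-mortality long-term survival,
    Guyot-style pseudo individual-patient-data reconstruction from digitized
    Kaplan-Meier curves with parametric refitting, vial-level drug costing,
    time-to-death utility weighting, a four-state partitioned-survival Markov
    engine over monthly cycles, and deterministic and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    flexsurv,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
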