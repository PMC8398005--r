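Package: ifxeval
Title: External Evaluation of Infliximab Population Pharmacokinetic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the external evaluation of published population
    pharmacokinetic models of infliximab and for Bayesian trough forecasting
    in therapeutic drug monitoring. Provides a registry of eight published
    one- and two-compartment infliximab models with their covariate,
    inter-individual variability and residual-error specifications; a
    closed-form prediction engine for arbitrary sequences of intravenous
    infusions (with a numeric ODE cross-check); a synthetic cohort generator
    emulating a real-world inflammatory-disease TDM population; population
    and MAP empirical-Bayes individual predictions; predictive-performance
    metrics (ME, MPE, RMSE, R2); simulation-based residual diagnostics
    (PWRES, IWRES, NPDE with the associated statistical tests);
    prediction-corrected visual predictive checks; and trough forecasting at
    future infusions with per-horizon error summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
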