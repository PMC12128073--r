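Package: vancoauc
Title: Trough-Based Vancomycin AUC Estimation with Pediatric Population
    Pharmacokinetic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates how well pediatric population-pharmacokinetic models
    recover the steady-state 24-hour vancomycin exposure (AUC24) from sparse
    therapeutic drug monitoring samples. Provides a compartmental
    pharmacokinetic engine with covariate models for intermittent intravenous
    infusion at steady state, maximum a posteriori (MAP) Bayesian estimation
    of individual parameters from zero, one or two concentrations, AUC24 and
    400-600 mg.h/L target-attainment computation, a four-scenario evaluation
    design (peak+trough, peak, trough, a priori) with median-consensus
    reference exposure and relative bias / relative root mean squared error
    metrics, and a synthetic neonatal/pediatric cohort generator so the full
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
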