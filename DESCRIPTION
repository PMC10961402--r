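Package: cetapkpd
Title: Pharmacokinetic and Pharmacodynamic Analysis of a Multiple-Dose
    DPP-4 Inhibitor Trial
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pharmacometric toolkit for phase-I multiple-dose
    trials of DPP-4 inhibitors. Provides non-compartmental pharmacokinetic
    analysis (linear-trapezoid AUC, best-fit terminal slope, accumulation
    ratios), pharmacodynamic summaries of DPP-4 inhibition, active GLP-1 and
    oral glucose tolerance testing, a pooled Emax concentration-effect model,
    and a nonlinear mixed-effects engine (Laplace approximation) for
    sequential population PK -> PK/PD modelling with stepwise covariate
    search, nonparametric bootstrap, conditional weighted residuals and
    visual predictive checks. A seeded virtual-trial simulator reproduces the
    14-day once-daily dosing design so the whole pipeline can be exercised
    and calibrated without subject-level data.
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
    minpack.lm,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
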