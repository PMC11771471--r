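Package: lateobd
Title: Phase I/II Dose Finding with Late-Onset Toxicity and Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Design and simulation of seamless phase I/II dose-finding
    trials in which both the binary dose-limiting toxicity (DLT) and the
    binary activity outcome may occur late in a multi-cycle follow-up
    period. Implements a joint time-to-event continual reassessment
    method that links weighted two-parameter logistic models for
    toxicity and activity through a Gumbel association model and selects
    the optimal biological dose (OBD) by a linear utility with a
    toxicity penalty. Comparator designs (the complete-follow-up joint
    CRM, a monotone dynamic-Beta model-assisted design, and a
    power-model design with working-model averaging and safety-gated
    adaptive randomisation), shared admissibility, enforcement and
    stopping rules, a correlated bivariate-lognormal outcome generator,
    and a trial simulator for operating characteristics are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
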