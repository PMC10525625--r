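Package: posapop
Title: Population Pharmacokinetics and Dose Optimization of Posaconazole
    in Lung-Transplant Recipients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of posaconazole
    therapeutic drug monitoring data and covariate-based dosing
    optimization. Implements a one-compartment first-order
    absorption/elimination structural model with closed-form multiple-dose
    and steady-state solutions, a hierarchical population layer with
    log-normal inter-individual variability and an age covariate on
    apparent clearance, SAEM-type maximum-likelihood estimation with
    importance-sampling likelihood and empirical Bayes estimates,
    covariate screening and stepwise model building, simulation-based
    model diagnostics (NPDE, VPC), and Monte Carlo probability of target
    attainment (PTA) simulation against trough and AUC/MIC targets with
    age- and indication-stratified regimen optimization. A synthetic
    cohort generator reproduces the covariate structure and sparse
    elimination-phase sampling design of a lung-transplant TDM study so
    the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    pracma,
    jsonlite
Config/testthat/edition: 3
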