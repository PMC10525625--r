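# posapop

Population pharmacokinetics and dose optimization of posaconazole in
lung-transplant recipients.

Lung-transplant patients receive posaconazole tablets for antifungal
prophylaxis or therapy, monitored by sparse therapeutic drug monitoring
(TDM). The clinical exposure targets differ by indication — a steady-state
trough above 0.7 mg/L for prophylaxis, above 1.25 mg/L for therapy, and an
AUC/MIC ratio of at least 200 (AUC24 ≥ 25 mg·h/L at the EUCAST
*Aspergillus* breakpoint of 0.125 mg/L) — and a uniform 300 mg daily dose
misses the therapy target in a meaningful share of patients. This package
implements the full analysis pipeline behind an age- and
indication-stratified dosing proposal, for pharmacometricians and clinical
pharmacologists who want to reproduce, stress-test, or extend it without
access to the original patient data.

## The model

One-compartment kinetics with first-order absorption and elimination, in
apparent (oral) parameters:

    C(t) = D·ka / (V/F·(ka − ke)) · (exp(−ke·t) − exp(−ka·t)),   ke = (CL/F)/(V/F)

with closed-form steady-state accumulation, a log-normal hierarchical
layer with an uncentered age effect on clearance,

    log CL/F_i = log CL/F_pop + β_age·age_i + η_CL,i,   η ~ N(0, ω²)

and proportional residual error y = C·(1 + b·ε). Defaults are the final
published model: ka 0.8 h⁻¹ (fixed, derived from summary kinetics via the
t_max relation), V/F 386.35 L, CL/F 8.8 L/h at the age-0 reference,
β_age −0.009/year, ω = 3.43/0.45/0.36, b = 0.29.

Around that core: a synthetic cohort generator matching the published
covariate summary and sparse elimination-phase sampling design; SAEM
maximum-likelihood estimation with importance-sampling objective function
and empirical Bayes estimates; Pearson/ANOVA covariate screening with
stepwise ΔOFV > 3.84 model building; NPDE and VPC diagnostics; and Monte
Carlo probability-of-target-attainment (PTA) simulation with per-stratum
dose optimization. The methods account lives in
`vignettes/posaconazole-poppk.Rmd`.

## Worked example

```r
library(posapop)
pop <- population_parameters()          # final-model estimates
p56 <- individual_params(pop, list(age = 56))
ss_trough(dosing_regimen(300, 24), p56) # 2.02 mg/L
ss_auc24(300, p56)                      # 56.4 mg*h/L

cohort <- generate_covariates(cohort_spec(), n = 32, method = "quantile", seed = 1)
sim <- simulate_population(pop, cohort, uniform_regimen_map(300),
                           n_replicates = 500, seed = 2)
compute_pta(sim, pkpd_target("trough", 1.25), "therapy")
```

```
Probability of target attainment: trough > 1.25 mg/L (therapy, observation scale)
  stratum     n n_attain   pta auc_median auc_q1 auc_q3
1  over60  4500     3821 84.9%       60.7   47.8   77.4
2 under60 11500     8793 76.5%       52.7   41.1   67.9
3 overall 16000    12614 78.8%       54.9   42.6   70.7
```

The typical 56-year-old on 300 mg daily sits at a 2.02 mg/L trough —
comfortably above the 0.7 mg/L prophylaxis threshold but with only 78.8 %
of the simulated population above the 1.25 mg/L therapy threshold once
inter-individual variability and measurement error are in play, and 76.5 %
in the under-60 stratum, where clearance is higher. Per-stratum dose
selection (here on the error-free model troughs) recovers the motivation
for stratified dosing:

```r
optimize_regimen(pop, cohort, seed = 2, trough_scale = "model")$detail
```

```
   indication age_stratum dose       pta attainable     n
1 prophylaxis     under60  200 0.9042609       TRUE 11500
2 prophylaxis      over60  200 0.9542222       TRUE  4500
3     therapy     under60  400 0.9331304       TRUE 11500
4     therapy      over60  300 0.9182222       TRUE  4500
```

`run_pipeline(pipeline_config())` chains the whole workflow — simulate a
cohort and TDM dataset, fit the base model, screen covariates, run
diagnostics, compare regimens, optimize doses — with every stage seeded
from one master seed.

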