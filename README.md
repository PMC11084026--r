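# akitraj

Trajectory-based classification of acute kidney injury (AKI) in critically
ill patients with sepsis.

KDIGO staging grades an AKI episode by its worst creatinine alone. This
package implements the longitudinal alternative: patients are classified by
the shape of the percent change in serum creatinine,
`pct(t) = 100 * (SCr(t) − SCr_ref) / SCr_ref`, over the first 96 h of ICU
admission, using a latent class mixed model (LCMM)

    y_ij = x(t_ij)' β_g + z(t_ij)' b_i + ε_ij,   b_i ~ N(0, D),  ε ~ N(0, σ²),

a finite mixture of linear mixed models with class-specific polynomial fixed
effects, shared random intercept and membership probabilities
`π_g = softmax(ξ)`. The class count is selected by BIC over G = 2–10, fitted
by a multi-start EM (grid-search burn-in, best start refined), and class
membership is then related to acute kidney disease (AKD — AKI persisting
past day 7) and composite AKD/mortality outcomes through logistic and Cox
models with predictive-mean-matching multiple imputation and Rubin pooling.

It is aimed at critical-care and nephrology researchers who want to apply
trajectory classes to their own long-format EHR extracts, or to study the
method itself. Because real ICU databases are credential-gated, the package
ships a synthetic cohort generator (`preset_published_classes()`) whose eight
latent classes, event streams and class-dependent outcome risks emulate the
published phenotypes, so the entire pipeline is testable offline. The full
toolchain is:

| stage | functions |
| --- | --- |
| simulate | `generator_config`, `preset_published_classes`, `generate_cohort`, `simulate_outcomes`, `write_cohort` / `read_cohort` |
| phenotype | `detect_suspected_infection`, `detect_sepsis_onset`, `compute_reference_creatinine`, `stage_creatinine`, `detect_aki`, `select_cohort`, `build_trajectory`, `determine_outcomes`, `phenotype_cohort` |
| model | `lcmm_spec`, `fit_lcmm`, `select_model`, `assign_classes`, `apply_lcmm`, `marginal_trajectories`, `write_lcmm_fit` / `read_lcmm_fit` |
| associate | `filter_missingness`, `impute_pmm`, `pool_rubin`, `fit_logistic_akd`, `fit_cox_composite`, `km_curves` |
| orchestrate | `pipeline_config`, `run_pipeline`, `write_report` (CLI wrapper in `inst/cli/akitraj.R`) |

## Worked example

```r
library(akitraj)

cfg    <- preset_published_classes(n_patients = 500, seed = 42)
cohort <- generate_cohort(cfg)
ph     <- phenotype_cohort(cohort)      # Sepsis-3 + KDIGO rules, trajectories
fit    <- fit_lcmm(ph$trajectories, lcmm_spec(G = 8), n_starts = 10,
                   tol = 1e-7, max_iter = 300, seed = 43)
asg    <- assign_classes(fit)
tab    <- merge(ph$cohort, asg$assignments, by = "patient_id")
fit_logistic_akd(tab)
```

which prints (among other things):

```
Synthetic ICU cohort: 500 patients, 8 latent classes (seed 42)
383 patients included; 117 excluded
Latent class mixed model: G = 8, degree 3, intercept random effects
  383 subjects; loglik -14318.09; BIC 28880.05; converged
OR of akd_day7 vs class 1 (unadjusted, m = 1)
 class estimate ci_low ci_high       p non_estimable
     2 2.78e-11  0.000     Inf 0.99974          TRUE
     3 2.17e+00  0.798    5.89 0.12932         FALSE
     5 3.61e+00  1.421    9.18 0.00699         FALSE
     7 4.25e+00  1.360   13.30 0.01281         FALSE
     8 5.74e+00  1.845   17.87 0.00255         FALSE
```

Reading this: 383 of 500 synthetic patients survive the cohort rules (the
rest are logged with one exclusion reason each, e.g. no qualifying sepsis
within 24 h, AKI after 48 h, death before 96 h). The eight-class LCMM
converges and assigns classes sharply (per-class mean posterior membership
probabilities, MPCMP, are ≥ 0.93 here). The odds ratios are AKD risk versus
class 1 (transient AKI): the severe persistent class 8 carries the highest
risk (OR 5.7 at this small n; the generator's configured value is 9.02), and
class 2 — which had no AKD events in this draw — is flagged `non_estimable`,
the package's complete-separation report. `run_pipeline(pipeline_config())`
wraps all of this, including the BIC sweep, imputation, Cox/KM models, a
consort-style manifest and a markdown report.

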