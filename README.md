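# vancoauc

Trough-based vancomycin AUC24 estimation with pediatric population
pharmacokinetic models.

## What this package is for

Pediatric vancomycin therapy targets a steady-state 24-hour area under the
concentration–time curve (AUC24) of 400–600 mg·h/L (at MIC 1 mg/L).
Model-informed precision dosing estimates that AUC24 by maximum a posteriori
(MAP) Bayesian fitting of a population PK (popPK) model to one or two
therapeutic drug monitoring samples. Blood draws are costly in neonates and
critically ill children, so the practical question is how much accuracy and
precision are lost when the AUC24 is estimated from a **single trough**
rather than a peak-and-trough pair — or from covariates alone.

`vancoauc` is a tidyverse-native toolkit for pharmacometricians and clinical
pharmacologists to answer that question by simulation and evaluation:

* a closed-form 1-/2-compartment engine for intermittent IV infusion at
  steady state, with a declarative YAML covariate-model format (power /
  allometric, sigmoidal postmenstrual-age maturation, linear terms; lognormal
  interindividual variability; additive / proportional / combined residual
  error) and age-dispatched creatinine-clearance estimates;
* a deterministic multi-start MAP estimator minimising the extended
  least-squares objective
  `Σ_j [(y_j − f_j(η))²/g_j² + ln g_j²] + ηᵀΩ⁻¹η`
  from 0, 1 or 2 concentrations;
* AUC24 (`daily dose / CL`) and 400–600 mg·h/L target-attainment
  classification;
* the four-scenario evaluation design (peak+trough, peak, trough, a priori)
  scored against a per-patient **median-consensus reference** (the median
  across candidate models of the peak+trough AUC24), with
  `rBias = 100·mean((pred−true)/true)` (bootstrap 95% CI, acceptable within
  ±15%) and `rRMSE = 100·√mean(((pred−true)/true)²)` (preferably < 20%),
  plus dosage-advice concordance;
* a synthetic cohort generator emulating two pediatric cohorts (neonates
  with postnatal age < 50 days; children ≥ 50 days) with realistic covariate
  ranges, steady-state peak/trough sampling, and hidden ground truth.

## Worked example

Simulate a 50-patient neonatal cohort from one bundled illustrative model
and evaluate a two-model candidate ensemble under all four TDM scenarios:

```r
library(vancoauc)

gen    <- example_model("neo_wt_pma_scr")
cohort <- simulate_cohort(gen, cohort_config("A", n = 50, seed = 42))
ev     <- run_evaluation(example_models("A"), cohort, eval_config(seed = 42))

glance(ev)
#> # A tibble: 1 × 4
#>   n_patients n_models median_true_auc24 pct_fits_converged
#>        <int>    <int>             <dbl>              <dbl>
#> 1         50        2              540.                100

dplyr::select(tidy(ev), model, scenario, n, rbias, rrmse, pct_concordant_advice)
#> # A tibble: 8 × 6
#>   model              scenario        n  rbias rrmse pct_concordant_advice
#>   <chr>              <fct>       <int>  <dbl> <dbl>                 <dbl>
#> 1 neo_wt_pma_scr     peak+trough    50  1.19   1.25                    98
#> 2 neo_wt_pma_scr     peak           50  3.15  16.0                     76
#> 3 neo_wt_pma_scr     trough         50  1.33   6.56                    92
#> 4 neo_wt_pma_scr     a priori       50  3.09  33.2                     60
#> 5 neo_wt_pma_scr_alt peak+trough    50 -1.19   1.25                    96
#> 6 neo_wt_pma_scr_alt peak           50  0.978 16.6                     68
#> 7 neo_wt_pma_scr_alt trough         50 -2.26   6.77                    90
#> 8 neo_wt_pma_scr_alt a priori       50 -3.84  34.1                     58
```

Reading the table: the consensus reference exposure has a median of
540 mg·h/L, inside the 400–600 target window. For both candidate models the
peak+trough scenario tracks the consensus almost exactly (rRMSE ≈ 1%), the
single trough loses only modest precision (rRMSE ≈ 7%, rBias within ±3%),
the single peak is clearly worse (rRMSE ≈ 16%), and a priori prediction from
covariates alone is the least precise (rRMSE > 30%) — the trough-only
sampling strategy holds up well. `autoplot(ev)` draws the rBias/rRMSE panel
with the ±15%/20% acceptability thresholds; `plot_auc_concordance(ev)` shows
model versus reference AUC24 with the target window shaded.

A thin command-line interface over the same functions is installed at
`system.file("cli", "vancoauc", package = "vancoauc")` with subcommands
`simulate`, `fit`, `evaluate`, `report` and `all`; every run writes a
manifest (seed, versions) and is byte-for-byte reproducible for a given
`--seed`.

See the vignette (`vignettes/trough-auc-evaluation.Rmd`) for the model, the
estimator, the evaluation design, and what the synthetic cohorts do and do
not emulate. The bundled models are illustrative — to evaluate specific
published models, encode them in the YAML format (`read_model()` /
`write_model()`).

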