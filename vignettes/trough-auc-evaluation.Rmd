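---
title: "Evaluating trough-based AUC24 estimation for pediatric vancomycin"
author: "vancoauc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating trough-based AUC24 estimation for pediatric vancomycin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vancoauc)
library(dplyr)
```

## The question this package answers

Vancomycin dosing in children is guided by the steady-state 24-hour area
under the plasma concentration–time curve, targeted to 400–600 mg·h/L (at an
MIC of 1 mg/L). In practice the AUC24 is not measured; it is estimated by
fitting a population pharmacokinetic (popPK) model to one or two therapeutic
drug monitoring (TDM) samples via maximum a posteriori (MAP) Bayesian
estimation. The clinically attractive option is a single trough sample; the
pharmacometrically safer option adds a post-distributional peak. `vancoauc`
implements the full machinery needed to quantify what is lost when the peak
is dropped: a compartmental PK engine with covariate models, a MAP estimator
that works with 0, 1 or 2 concentrations, AUC24 and target-attainment
computation, a four-scenario evaluation design with a median-consensus
reference exposure, and a synthetic pediatric cohort generator so the whole
pipeline is testable without patient data.

## The pharmacokinetic model

Disposition is linear (first-order elimination; nonlinear elimination is out
of scope) with one or two compartments, dosed by intermittent intravenous
infusion. For a single infusion at rate $R_0$ over duration $t_{inf}$, the
plasma concentration is a sum over exponential modes $(c_i, \lambda_i)$:

$$
C(t) = R_0 \sum_i \frac{c_i}{\lambda_i}
\left(1 - e^{-\lambda_i \min(t,\,t_{inf})}\right)
e^{-\lambda_i \max(t - t_{inf},\,0)} ,
$$

with a single mode $c = 1/V_1$, $\lambda = CL/V_1$ for one compartment and
the usual $\alpha/\beta$ macro-constant pair for two compartments. Multiple
doses superpose; the periodic steady state sums the infinite dose history as
a geometric series per mode, so no dose-by-dose simulation is needed
(`conc_ss()`). Times beyond the scheduled interval are accepted and give the
concentration when the next dose is held, because late troughs are a routine
feature of real TDM data. The closed forms are verified in the test suite
against adaptive ODE integration (`deSolve::lsoda`, segment-wise across the
infusion discontinuity) to a relative error of $10^{-5}$, and the ODE route
is retained only as that oracle — it is never used in the pipeline.

Each structural parameter is a typical value multiplied by covariate terms:
power/allometric terms $(x/x_{ref})^{k}$, a sigmoidal maturation term on
postmenstrual age $PMA^\gamma / (PMA^\gamma + TM_{50}^\gamma)$, and linear
terms. Interindividual variability is lognormal,
$P_i = P_{pop}\,e^{\eta}$ with $\eta \sim N(0, \Omega)$ — the universal
convention for this model class. Renal function, where a model asks for it,
is estimated from serum creatinine by an age-dispatched bedside formula:
below 365 days of postnatal age an infant formula with an age-dependent
coefficient $k = 0.0414\,\ln(\text{PNA in days}) + 0.3018$ applied as
$k \cdot \text{height} / S_{Cr}$ (creatinine converted to mg/dL), and from
365 days the bedside Schwartz equation
$0.413 \cdot \text{height} / S_{Cr}$. The two do not agree at the boundary;
the handoff (boundary day assigned to Schwartz) is a documented
discontinuity matching how the estimators are used clinically. The infant
formula is pluggable — pass any `crcl` value directly to bypass it.

The package deliberately ships no re-encoding of published models: their
parameters live in their original publications. Instead it defines a
declarative YAML model format (validated on load, exact round-trip on write)
and bundles five illustrative models mirroring the covariate composition
reported for this population — neonatal one-compartment models with weight,
PMA maturation and creatinine on clearance, and pediatric models with
allometric weight (± creatinine or creatinine clearance), one of them
two-compartmental. Their parameter values are the implementer's choices,
picked to produce realistic pediatric exposures (clearance ≈ 0.06 L/h/kg in
term neonates, ≈ 0.1 L/h/kg in children; volume ≈ 0.5–0.6 L/kg).

## MAP estimation

Individual random effects are the posterior mode:

$$
\hat\eta = \arg\min_\eta \;
\sum_j \left[ \frac{(y_j - f_j(\eta))^2}{g_j^2} + \ln g_j^2 \right]
+ \eta^\top \Omega^{-1} \eta ,
$$

where $f_j$ is the steady-state model prediction at observation $j$ and
$g_j$ the residual standard deviation there (additive, proportional, or
combined). The $\ln g_j^2$ term makes the objective the extended
least-squares form, so proportional-error fits are proper. With no
observations the minimiser is $\eta = 0$ exactly — the a priori scenario is
the prior mode by construction, not by optimisation.

Numerical choices: the objective is smooth, so `estimate_map()` runs BFGS
with numerical gradients from the prior mode plus four jittered starts
(drawn once from a fixed seed, default 101 — the estimate is fully
deterministic); one-dimensional problems use Brent on $[-15, 15]$. Ties
within $10^{-8}$ in the objective break toward the smallest $\lVert\eta\rVert$.
Non-convergence after all starts flags the fit, and the pipeline excludes
flagged fits with a logged reason rather than imputing. A singular $\Omega$
is an error unless an eigenvalue pseudo-inverse is explicitly enabled
(`map_control(pseudo_inverse = TRUE)`). Optimizer tolerances are package
configuration, not scientific claims; the tests verify the optimizer against
an exhaustive 10 001-point grid search to within $10^{-3}$.

## Exposure and the evaluation design

For linear PK at steady state, AUC24 is simply daily dose / CL — independent
of volumes and of how the day is split into intervals, which is why τ = 6, 8
and 12 h regimens are all comparable through it. The 400–600 mg·h/L window
is applied with inclusive boundaries (the target is stated as "400 to 600"
without boundary semantics; the choice is centralised in `eval_config()`).

`run_evaluation()` fits every candidate model to every patient under four
scenarios — peak+trough, peak only, trough only, a priori — and scores each
model × scenario cell against a per-patient reference exposure: the median
across models of the peak+trough AUC24 estimates (mean of the two middle
values for even ensembles). Because no measured AUC exists in sparse TDM
data, this median-consensus construction is the reference; it is also the
design's main limitation, since poorly performing models pull on the
consensus (mitigated, but not removed, by the median).

Performance metrics are the field-standard pair, in percent:

$$
\text{rBias} = \frac{100}{n}\sum_i \frac{pred_i - true_i}{true_i},
\qquad
\text{rRMSE} = 100\sqrt{\frac{1}{n}\sum_i
\left(\frac{pred_i - true_i}{true_i}\right)^2}.
$$

rBias is signed (accuracy; acceptable within ±15%), rRMSE is quadratic
(precision; preferably < 20%). Note that rRMSE ≥ |rBias| is *not* an
invariant worth asserting beyond the Cauchy–Schwarz direction; the metrics
answer different questions and are reported side by side. The rBias 95%
confidence interval is a patient-level nonparametric bootstrap (2 000
resamples, percentile method, seeded from `eval_config()`); patients are
sorted by id before resampling so the metrics are invariant to input order.

Dosage-advice concordance classifies both the model AUC24 and the reference
into below/within/above the target window and counts agreement. Two related
statistics are reported because the underlying clinical quantity ("patients
not requiring dosage adjustment") is ambiguous: `pct_concordant_advice` (any
band agreement) and `pct_no_adjustment` (both values within the window).
Neither is claimed to be the uniquely correct reading.

## What the synthetic cohort emulates — and what it does not

The generator produces two cohorts shaped like real pediatric TDM
populations: cohort A, neonates and young infants (postnatal age < 50 days,
weight 0.7–4.2 kg, gestational age 25.4–41 weeks, serum creatinine 15–81
µmol/L, dose 5.8–26.9 mg/kg) and cohort B, older infants to adolescents
(postnatal age ≥ 50 days, weight 2.3–74.6 kg, creatinine 6–103 µmol/L, dose
5.8–33.5 mg/kg). Only medians and ranges of the emulated population are
known, so the distribution families are generator choices, documented in
`cohort_config()` and fully overridable: uniform postnatal age and
triangular gestational age (mode 37 weeks) in cohort A with
PMA = GA + PNA/7; lognormal postnatal age in cohort B with weight and height
tied to age through standard pediatric growth approximations; truncated
lognormal creatinine and dose per kg. Weight correlates with maturity;
creatinine is drawn independently given age, since the real correlation
structure is unreported. Dosing intervals follow a simple plausible policy
(cohort A: 12 h below 37 weeks PMA, else 8 h; cohort B: 6 h below 12 years,
else 8 h) — the interval only enters through daily dose and sampling times.

Each virtual patient receives one peak sample (lognormal delay after the end
of infusion, median 0.6 h, truncated to the early post-distributional window)
and one trough (0.1–0.9 h before the end of the interval), simulated at
periodic steady state from the generating model's individual parameters and
corrupted with residual noise truncated below at 0.05 mg/L. The default
simulation noise is assay-level measurement error (combined, 0.5 mg/L + 10%)
rather than the generating model's fitted residual: a fitted popPK residual
also absorbs model misspecification and residual-time errors, so using it to
corrupt simulated samples would overstate measurement noise; pass
`residual = "model"` to simulate with the model's own residual instead. An
optional time-registration error mode (`time_error_sd = 5/60`) perturbs the
*recorded* times by up to ±5 minutes while concentrations are simulated at
the true times, emulating charting uncertainty.

Steady state is imposed by construction (closed-form periodic solution)
rather than by simulating the 1–184 preceding doses real patients had; this
mirrors the extrapolation used when such data are analysed. The generator
does not emulate ECMO or continuous hemofiltration physiology, continuous
infusion, within-day creatinine dynamics, missing or mislabeled samples, or
model-misspecification structure beyond what distinct candidate models
provide. Consequently, passing tests demonstrate the *machinery* —
estimator, exposure arithmetic, scenario logic, metrics — under controlled
conditions; they cannot certify any particular published model for clinical
use on real data.

## What the checks compute

The test suite verifies, among other properties: closed-form kinetics
against ODE integration (100 randomised cases, relative error ≤ 10⁻⁵ above a
10⁻⁴ mg/L floor); analytic AUC24 against fine-grid trapezoid integration of
the steady-state profile (50 regimens, ≤ 0.5%); MAP estimates against
exhaustive grid search (10 001 points per dimension in 1-D, a two-stage
exhaustive grid in 2-D, agreement 10⁻³); exact hand-computed metric values;
self-consistency (a noise-free cohort evaluated with its generating model
has peak+trough rBias and rRMSE of 0 to numerical tolerance); AUC24 recovery
against the generator's hidden truth (200 patients at low noise: |rBias| ≤
2%, rRMSE < 5%); the scenario ordering on the default synthetic cohort (100
patients, two-model neonatal ensemble: the a priori rRMSE exceeds both the
trough-only and peak+trough rRMSE); and byte-identical output tables across
repeated seeded runs. These problem sizes are the package's chosen test
conditions; larger cohorts behave the same way and can be run through
`scripts/acceptance.R` or the CLI.

A worked end-to-end example:

```{r example, eval = FALSE}
gen <- example_model("neo_wt_pma_scr")
cohort <- simulate_cohort(gen, cohort_config("A", n = 100, seed = 42))
ev <- run_evaluation(example_models("A"), cohort)
tidy(ev)                  # metrics per model x scenario
glance(ev)                # cohort-level summary
autoplot(ev)              # rBias / rRMSE panel with thresholds
plot_auc_concordance(ev)  # model vs reference AUC24, target window shaded
```

## Known limitations

* The consensus reference is only as good as the candidate ensemble; with
  few or similar models it degenerates toward a single model's estimate (a
  property the tests exercise deliberately).
* The bundled models are illustrative. Conclusions about specific published
  models require encoding those models in the YAML format from their
  original publications.
* MAP shrinkage biases individual estimates toward the population mode when
  data are sparse or residual noise is large; the recovery checks quantify
  this only under the generator's conditions.
* The engine is restricted to intermittent IV infusion with linear
  elimination and time-constant covariates within the evaluation day.
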