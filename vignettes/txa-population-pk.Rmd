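---
title: "Population pharmacokinetics of intravenous tranexamic acid in obstetric hemorrhage: models and methods"
author: "txapopk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK of tranexamic acid: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model family, the estimation machinery, the synthetic-trial generator
that stands in for patient data, and the numerical and design choices
made where the methodology left them open. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The clinical problem and the data layout

Tranexamic acid (TXA) is given as a 0.5 g or 1 g intravenous bolus over
one minute once postpartum blood loss during caesarean delivery exceeds
800 mL. The analysis dataset is an event-record table: per subject, one
dosing event at T0 (plus a possible rescue dose when bleeding worsens),
six venous plasma samples nominally at 15, 30, 60, 120, 180 and 360 min
(each within ±10 min), and two urine collections within six hours. Urine
is observed as a concentration over a half-open collection interval
`(t_start, t_end]` together with the collected volume, so the model
quantity behind a urine observation is an amount difference:

```
y_urine = (Au(t_end) - Au(t_start)) / V_collected
```

This interval-concentration convention is an explicit package choice: the
source methodology never states its urine observation equation, and the
amount-difference form is the only one consistent with a cumulative urine
compartment and a measured volume. It is also what the generator
simulates, so the fitting and simulation paths share one definition.

Times are minutes from the first dose. Serum creatinine is stored in
mg/L; the reported baseline values (~6.5) are only numerically consistent
with mg/L (0.65 mg/dL), and the renal formulas convert internally.

## 2. Structural model family

Candidate topologies combine 1–3 compartments with (i) a urinary
elimination from the central compartment, first order or saturable,
observed through the urine stream; (ii) an optional non-urinary
first-order route from the central compartment; and (iii) an optional
elimination from the first peripheral compartment (structurally
motivated by loss into uterine hemorrhagic blood, which has no data
stream of its own). The selected model is the two-compartment spec with
double first-order central elimination.

Rather than estimating two separate clearances, the package parameterizes
the *total* central elimination clearance `CL` and the urinary excretion
fraction `p_urine`, with `k_urine = p_urine * CL / V1`. This matches how
the final estimates are reported (CL and `theta_purine` jointly) and
keeps the urinary/non-urinary split inside `[0, 1]` by construction.

Linear specs are evaluated in closed form: the mammillary disposition
matrix is eigen-decomposed (quadratic for two compartments, trigonometric
cubic for three), each zero-order infusion contributes per-mode terms,
and the cumulative urinary amount integrates the same modes analytically.
The 1-minute bolus is always represented as a 1-minute zero-order
infusion, because the injection duration was controlled strictly and the
end-of-infusion time anchors the concentration peak. Rescue doses are
handled by event superposition at their recorded times. The
Michaelis–Menten variants have no closed form and are integrated with
`deSolve::lsoda` at relative tolerance `1e-8`; the same ODE path doubles
as the independent oracle for the closed-form evaluator in the test
suite (agreement to `1e-6` relative is asserted at the published typical
parameters).

The terminal half-life is `ln 2 / lambda_z` with `lambda_z` the slowest
disposition eigenvalue *among modes that contribute to the plasma
response* (modes with a bolus-response AUC share below `1e-6` are
ignored). The filter matters only in degenerate corners — e.g. as the
diffusional clearance goes to zero the slow mode's amplitude vanishes and
the half-life must converge to the one-compartment value.

## 3. Mixed-effects model and SAEM engine

Observations follow `y = f + g * eps` with `eps ~ N(0, 1)`. Plasma uses a
combined error `g = sqrt(a1^2 + b1^2 f^2)`, urine a proportional error
`g = b2 f`; additive and exponential models are available for both
streams (the exponential model is implemented as additive error on the
log observation, and a test asserts that identity against a hand-written
log-normal density).

Individual parameters are log-normal around covariate-adjusted population
values. The one deviation from a blanket log-normal convention is
`p_urine`, whose random effect lives on the logit scale: with a fixed
effect of 0.54 and a BSV near 46%, a log-normal fraction would place
appreciable mass above 1. The reported fixed effect is still the natural
fraction (`plogis` of the location), so published values remain directly
comparable. The generator and the fitter share the convention.

Estimation is stochastic approximation EM:

* **Schedule** — 400 exploratory iterations (step size 1) followed by 200
  smoothing iterations (step `1/(k - 400)`); simulated annealing bounds
  the per-iteration shrinkage of `omega` and error parameters to a factor
  0.95 during exploration. The methodology names the algorithm but no
  schedule; these defaults are conventional and configurable via
  `saem_control()`.
* **Conditional sampler** — 5 independent MCMC chains per subject (the
  stated chain setting), each advanced 2 transitions per iteration: an
  independence kernel proposing from the conditional prior, then a
  componentwise random walk whose scales adapt toward 30% acceptance
  during exploration.
* **M-step** — exact weighted least squares per parameter for the
  location/covariate coefficients and `omega`; closed-form updates for
  additive/proportional/exponential error; Nelder–Mead on the
  complete-data likelihood for the combined error, followed by
  stochastic-approximation smoothing of the parameter itself.
* **Starting values** — NCA-informed heuristics (`CL ~ dose/AUC`,
  `V1 ~ dose/Cmax`, `omega = 0.3`, `p_urine = 0.5`); recovery experiments
  never start at the generative truth.

Everything downstream of the stochastic phase is deterministic given the
seed: conditional means/modes and samples (120 sampler iterations, 20
burn-in), a linearized Fisher information (finite differences around the
conditional modes; fixed-effect block `sum F' V^-1 F`, variance block
`0.5 tr(V^-1 dV V^-1 dV)`), RSE% on the natural reporting scale, and the
condition number `kappa` as the eigenvalue ratio of the estimates'
correlation matrix (`kappa > 100` flags over-parameterization, the
retention guard used in covariate selection).

`-2 log L` is estimated by per-subject importance sampling with a
multivariate t(5) proposal centered on the conditional modes and scaled
by the conditional-sample covariance (10,000 draws by default as a
standalone operation; 2,000 inside a fit, where the value only feeds
model ranking and the Monte Carlo SE is reported alongside).

**BICc.** Model comparison uses a hybrid-penalty BIC: fixed effects and
covariate coefficients are penalized by `log(N subjects)`, variance and
residual-error parameters by `log(total observations)`. This grouping
reproduces exactly (to printed rounding) the criterion values published
for both the base-model screen and the covariate ledger, which is how the
package fixed the grouping when the verbal description alone was
ambiguous. The improvement threshold is 3.84, the 5% chi-square point
with one degree of freedom.

**Shrinkage** is `1 - var(conditional-mean eta)/omega^2` per random
effect, the variance taken across subjects — near 0 under rich sampling,
100% for subjects carrying no information.

## 4. Covariate machinery

Candidates pair a target parameter with a panel column in one of two
forms on the log scale: `log psi = log theta + beta * x` (exponential on
the natural scale, covariate *uncentered* — so `theta_CL` is the
extrapolated eClcr = 0 intercept, exactly as the final equation is
printed, non-physiological as that intercept is) or
`log psi = log theta + beta * log(x / ref)` (a power relation, `ref = 70`
kg for weights). The panel derives, for each subject and twice where
weight enters (pre-pregnancy and at caesarean): BMI; ideal weight
(Devine, female); adjusted body weight `IW + 0.4 (W - IW)`; lean body
weight (Janmahasatian, female); BSA (Du Bois); Cockcroft–Gault creatinine
clearance (female); CKD-EPI 2009 and MDRD-4 eGFR (female), de-indexed
from mL/min/1.73 m² to absolute mL/min via `BSA/1.73` — de-indexing is
the only reading under which the two published eGFR columns (one per
weight) differ, since both formulas are themselves weight-free.

Forward selection adds one relation at a time, refitting each candidate
warm-started from the current model (a shortened schedule of 150 + 75
iterations with 2 chains is the default for these refits). A round's best
candidate is retained only if it lowers BICc by ≥ 3.84 with `kappa < 100`
and a Wald-significant coefficient; ties break by BICc, then `kappa`,
then label (the methodology is silent on ties). Candidates whose fit
errors are recorded as non-evaluable and selection continues. Subjects
with missing weight or creatinine are excluded from the selection dataset
but remain available for base-model fitting, mirroring the design's
84 → 79 subject reduction.

## 5. Validation diagnostics

* **VPC** — replicate trials simulated on the observed design; observed
  10/50/90th percentiles per time bin against each percentile's
  simulation band. Bins default to the nominal sampling times whenever
  all observations lie within the ±10 min design window of one, else
  quantile bins (the binning rule is a package choice).
* **NPDE** — per-subject decorrelation by the Cholesky factor of the
  empirical simulation covariance (chosen over an inverse square root for
  determinism; a ridge is added with a warning if the covariance is
  singular), rank transform against the simulations, then the
  standard-normal quantile function. Plasma and urine streams are
  reported separately (mean, variance, Shapiro–Wilk, fraction outside the
  central 90% interval).
* **Bootstrap** — case resampling of subjects with replacement,
  stratified by dose arm so the 34/45 split is preserved (the methodology
  does not state stratification; preserving the arm sizes keeps every
  replicate estimable for both doses). Replicates refit the *final*
  covariate structure only — whether the original procedure re-selected
  covariates per replicate is unstated, and refitting the fixed structure
  is the conventional reading. Failures are excluded and counted, with a
  validity warning above 20%.

## 6. Noncompartmental analysis

Partial AUCs use the linear-up/log-down trapezoid (log rule on strictly
declining positive segments, linear otherwise, including a documented
linear fallback around non-positive values). Boundary values at 30 and
60 min, and the end-of-infusion peak `C_T1`, are interpolated or
back-extrapolated log-linearly on declining data. `C_T1` is defined from
the observed samples (a model-predicted peak is available by evaluating
`predict_profile` at the end of infusion instead, since the printed
wording is ambiguous about which was used). The terminal half-life
regresses the last three declining positive points; MRT is `AUMC/AUC`
over the observed span only — a *truncated* MRT, deliberately not
extrapolated to infinity given the 6-hour design. Bleeding-status group
comparisons use Kruskal–Wallis at 5%; group labels are inputs (generated
synthetically in tests), not adjudicated by the package.

## 7. Dose simulation

`simulate_population()` samples covariates from the baseline generator,
applies the final covariate model with between-subject variability, and
evaluates each subject on a 1-minute grid over 0–360 min. Threshold
coverage (e.g. "fraction holding ≥ 30 mg/L through 15 min") is computed
*without* residual assay error — coverage is a statement about the
underlying concentration, not the measurement; a flag restores the error.
The window starts at the end of infusion, since concentrations during the
1-minute administration rise from zero by construction.

Simulations use the final covariate model: it is the only structure whose
between-subject variances are fully reported. One published summary-table
quirk matters for cross-checking: the two printed dose rows are
transposed relative to their labels (the row labeled 0.5 g carries the
concentrations only a 1 g bolus can produce, and the measured 15-min
range for 0.5 g matches the row labeled 1 g). The package reports doses
unambiguously and the test suite compares the 1 g simulation against the
swap-corrected row.

## 8. The synthetic trial generator

`generate_trial()` defines the study conditions used throughout the test
suite and the acceptance script:

* 34 + 45 subjects in the 0.5 g / 1 g arms; covariates drawn from
  truncated normals at the published per-arm baseline moments (inverse-CDF
  sampling, so the draws are exact). Distribution shapes are unstated in
  the source; truncated normals are this module's choice and are confined
  to it. Weight gain during pregnancy is an independent truncated normal
  (mean 11 kg, SD 4 kg) calibrated so the at-caesarean weight moments
  match the published ones; bleeding volume is truncated at the 800 mL
  inclusion threshold. Truncation bounds are physiological (e.g. weight
  floor 30 kg) and chosen so cohort means stay within a fraction of an SD
  of their targets.
* Plasma sampling at the six nominal times jittered uniformly within
  ±10 min (never before the end of infusion); urine collections over
  `(0, 180]` and `(180, 360]` min with log-normal volumes (median 0.4 L)
  — the design says only "two collections within 6 h", so the interval
  split and volume law are generator choices.
* Rescue doses with probability 8/79, at a log-normal time with median
  87 min, amount equal to the subject's arm dose; the one double-rescue
  subject of the real trial is not emulated by default.
* Observations carry the model's stated error structure; additive noise
  can produce a negative concentration, which is truncated at zero and
  *counted* rather than resampled, to keep the error model honest.
* The hidden individual parameters are returned for recovery scoring.

What the generator deliberately does **not** emulate: assay quantification
limits (no BLQ handling anywhere, none was reported), within-subject
covariate dynamics, correlated random effects (the reported `omega` is
diagonal), uterine-blood drug loss as an observable, or dropout. Passing
recovery tests therefore demonstrates internal consistency of estimation
under the declared generative mechanism — not robustness to features of
real data outside that mechanism.

## 9. Problem sizes and numerical choices in the test suite

The suites fit 79-subject trials at full fidelity but use shortened,
still-honest SAEM schedules where many fits are repeated (250 + 100
iterations with 3 chains for the ten replicate recoveries; 200 + 100 for
the five-way structural ranking; 150 + 75 with 2 chains for candidate
refits inside forward selection; 120 + 60 for bootstrap replicates, 50
replicates in the scaled bootstrap property). Importance sampling uses
1,000–2,000 draws per subject in these loops. These sizes are the
package's reproducibility choices; the defaults remain 400 + 200 × 5
chains and 10,000 draws. All tests fix seeds, and seeded determinism
(bit-identical refits) is itself asserted.

Degenerate inputs are handled explicitly: zero doses give identically
zero profiles; `omega = 0` removes a random effect (and the marginal
likelihood then evaluates directly, a tested identity); constant
covariates are skipped in screening; singular candidate designs surface
as non-evaluable selection rows; a failed information matrix reports
`kappa = Inf` rather than silently passing.

## 10. Known limitations

* SAEM covers the linear structural specs; saturable variants are
  constructible and simulatable but not fittable (the original nonlinear
  candidates partly failed to converge in the source analysis as well).
* No inter-occasion variability, no off-diagonal `omega`, no BLQ/censored
  observations, no multi-analyte records, no covariate-uncertainty
  propagation.
* The FIM is a first-order linearization around conditional modes; for
  very sparse designs its RSEs can be optimistic relative to a stochastic
  information estimate.
* `theta_CL` is an extrapolated eClcr = 0 intercept by construction of
  the uncentered exponential relation; it should not be read as a
  physiological anuric clearance.
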