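---
title: "Models and methods behind cetapkpd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cetapkpd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cetapkpd)
```

# Scope

`cetapkpd` implements the complete pharmacometric analysis of a phase-I
multiple-dose trial of an oral DPP-4 inhibitor in patients with type 2
diabetes: 32 subjects in two 16-subject dose groups (50 and 100 mg),
randomised 10:2:4 to active drug, placebo or an open-label comparator
gliptin, dosed once daily for 14 days, with rich plasma sampling on days 1
and 14, trough samples on days 7 and 10, and oral glucose tolerance tests
(OGTT) before and after treatment. The pipeline covers:

1. non-compartmental PK analysis (NCA),
2. pharmacodynamic summaries of DPP-4 inhibition, active GLP-1 and OGTT
   analytes,
3. a pooled Emax concentration-inhibition model,
4. a sequential population PK -> PK/PD nonlinear mixed-effects analysis
   with stepwise covariate search, bootstrap, CWRES diagnostics and visual
   predictive checks (VPC).

Because no subject-level data are publicly deposited, the package ships a
seeded virtual-trial generator (`simulate_trial()`) that emulates the
study design; every downstream stage is exercised and tested against it.

# Data model

All stages exchange a single rectangular event-record table
(`study_dataset()`): one row per dose (`EVID = 1`) or observation
(`EVID = 0`), NONMEM-style columns (`ID`, `TIME`, `AMT`, `DV`, `DVID`,
`MDV`, `BLQ`, `OCC`) plus subject-constant covariates (total bilirubin
`TBIL` is mandatory). Time is decimal hours since the first dose; baseline
days are negative. Pre-dose samples ("within 0.5 h before dosing") are
placed at the nominal dosing time. BLQ policy: pre-first-dose BLQ values
count as zero, BLQ values from Tmax onwards are excluded from NCA and from
likelihood evaluation.

# Non-compartmental analysis

All areas use the linear trapezoid (one shared code path,
`auc_linear()`), exact for piecewise-linear data, with linear
interpolation at interval bounds. The terminal slope uses the
"best fit" convention of the standard NCA tools: every terminal window of
the last k >= 3 points strictly after Tmax is regressed on the log scale
and the window with the highest adjusted R^2 wins, ties going to the
longer window.
Estimates spanning fewer than two half-lives are flagged unreliable rather
than suppressed. Steady-state parameters follow the standard identities
`Cav,ss = AUC0-tau/tau`, `CLss/F = Dose/AUC0-tau`,
`Vz,ss/F = CLss/F / lambda_z`. Note that the single-dose definition
`CL/F = Dose/AUC0-inf` is also computed (`cl_f`); published steady-state
clearances in this drug class are consistent only with the
`Dose/AUC0-tau` definition, so the steady-state table uses `clss_f`.
Accumulation ratios are `Cmax(day 14)/Cmax(day 1)` and
`AUC0-tau(day 14)/AUC0-24(day 1)`.

# Pharmacodynamic metrics

DPP-4 inhibition is the relative drop from the subject's day-1 pre-dose
activity, `(1 - activity/baseline) * 100`; supra-baseline values give
negative inhibition and are retained (truncation would bias residual
estimates). `DUR80` integrates the time above 80% inhibition with
piecewise-linear crossing interpolation — over the dosing interval on
day 1 and over the full sampled extent (to 120 h) on day 14, where
inhibition persists beyond the interval. `E24` is read (or linearly
interpolated, and then flagged) at 24 h. GLP-1 change scores are
`value(t) - value(0)` with post-meal readings at t = 6 and 12 h (2 h after
the 4 h and 10 h meals); the day-14 average response is defined as
`AUEC0-24/24`, which reproduces published GLP-1 summary arithmetic
exactly (57.8/24 = 2.408). OGTT effect areas are plain AUEC0-3h per
analyte; treatment effects are day-15 minus day-(-1) differences averaged
by arm.

# The nonlinear mixed-effects engine

Individual parameters are lognormal, `P_i = P_pop * exp(eta_i)`, with a
diagonal covariance for `eta` (no omega blocks). Residual error is
additive, proportional or combined; the combined model contributes
variance `sigma_add^2 + sigma_prop^2 * IPRED^2` (independent components).
The marginal -2 log-likelihood is computed per subject by the Laplace
approximation at the posterior mode of `eta`:

* the mode is found by a damped Newton iteration whose gradient is
  analytic given a central finite-difference Jacobian of the structural
  prediction (step 1e-4 on the `eta` scale);
* the curvature matrix is the Gauss-Newton (expected) Hessian assembled
  from the same Jacobian, including the residual-variance derivative
  terms of the proportional model. Second derivatives of the structural
  prediction are dropped — exact for models linear in `eta`, the standard
  expected-Hessian approximation otherwise. On any linear-Gaussian
  sub-model the resulting OFV equals the closed-form marginal -2LL to
  ~1e-11, which the test suite asserts.

The outer problem optimises fixed effects (log scale for positive
parameters, logit for the inhibition ceiling, identity for covariate
exponents), log-variances and log-sigmas with `nlminb`. The default
relative tolerance is 1e-6: the inner approximation leaves a noise floor
of order 1e-6 on the objective, and tighter settings stall in
"false convergence" without moving the estimates. A variance is reported
as at the boundary when its log falls below -10. Standard errors come
from the finite-difference Hessian of the OFV (`RSE% ~ 100 * SE(log)` for
lognormal parameters); a singular Hessian yields missing RSEs, flagged in
the convergence report.

CWRES uses the first-order-conditional linearisation about the posterior
mode: residuals are decorrelated by the inverse matrix square root of
`J Omega J' + V(IPRED)`. With all random effects at zero this reduces to
`(DV - PRED)/sigma`. Observations with `|CWRES| > 5` are treated as
outliers when assembling the sequential PK/PD dataset, mirroring common
regulatory practice.

# Population PK model

The structural model is a two-compartment disposition with first-order
absorption, solved in closed form (tri-exponential single-dose solution
superposed over the dose history; rate collisions take a continuous limit
branch). All parameters are apparent (/F), bioavailability fixed at 1.
Between-subject variability sits on `cl`, `v1` and `v2`; with the first
post-dose sample at 0.5 h the absorption rate constant is not estimable
and is fixed by default (`ka_fixed = TRUE` in `pk_twocomp_model()`), and
`ka` carries no random effect. Covariates enter as power functions
normalised to the cohort median,
`P_i = theta * (cov/reference)^exponent`, the conventional scale-free
choice. The stepwise search uses forward inclusion at dOFV >= 3.84
(p ~ 0.05, 1 df) and backward elimination at dOFV < 6.63 (p ~ 0.01),
both configurable; candidate fits that fail to converge are skipped and
logged, never accepted silently.

# Sequential PK/PD

The sequential method is IPP: individual PK parameters are frozen at
their empirical Bayes estimates, each inhibition observation is paired
with the subject's predicted concentration at its time, and the
sigmoid-Emax direct-effect model
`E = Emax * C^gamma / (EC50^gamma + C^gamma)` is fitted with lognormal
variability on `EC50` (the ceiling `Emax` sits near a physical bound and
gets none; it is optimised on a logit scale over (0, 100]) and combined
residual error. The pooled two-parameter Emax analysis (`fit_emax()`)
is separate: unweighted least squares on pooled
concentration-inhibition pairs with the Hill coefficient fixed at 1,
multistart initialisation (ceiling from {max observed, 100}, `EC50` on a
log-grid over the observed concentrations), pooling day-1 and day-14
pairs by default (switchable by occasion).

# Model evaluation

The nonparametric bootstrap resamples whole subjects with replacement,
stratified by arm by default so arm sizes are preserved (the unstratified
variant is a flag); non-converged replicates are excluded and counted.
B defaults to 1000, with 500 available where a lighter preset is wanted.
The VPC simulates replicate trials under the fitted model with the
original design and fresh random-effect and residual draws, bins by the
nominal sampling times (the design is fixed-schedule, so no adaptive
binning), and is uncorrected (no prediction correction). All random draws
flow from explicit seeds; every evaluation tool is bit-reproducible given
its seed.

# The virtual-trial generator

`sim_config()` fixes the design: arm sizes 10/10/8/4, fourteen daily
doses, the day-1/7/10/14 sampling grids, OGTT at
{0, 0.167, 0.5, 1, 1.5, 2, 3} h on day -1 and day 15, meals at 4 and 10 h
post-dose on sampled days. GLP-1 is simulated at the day-1 and day-14
sampling times up to 24 h post dose, where meals are defined.

The true PK parameters are a deliberate calibration, not published
estimates: the generator's defaults were chosen (by iterating
simulate -> NCA/PD summary) so that simulated group means of the active
arms land on the published summary magnitudes — steady-state Cmax and
AUC0-24h at both doses, day-1 AUC, day-14 inhibition AUEC and the
duration of >80% inhibition. Two features of that calibration deserve
note:

* The published steady-state table implies a concentration curve that
  falls with an effective half-life of roughly 15-20 h between 24 and
  48 h post dose while the reported terminal half-life (from the late
  tail) is ~35-42 h. A dose-proportional two-compartment model can meet
  the trough dynamics, the day-1 exposure and the accumulation ratio
  simultaneously only with a pronounced fast phase; the calibrated
  defaults therefore carry a small apparent central volume and fast
  absorption, and their NCA terminal half-life is shorter than the
  published one (neither Cmax on day 1 nor t1/2 is a calibration
  target).
* The inhibition link uses the published pooled potency (ceiling 92.47%,
  EC50 5.37 ng/mL) with a Hill coefficient slightly below 1; group-mean
  durations above 80% inhibition are sensitive to between-subject
  variability because the day-14 trough sits close to the threshold, so
  the generator's variability defaults are modest (exposure CV ~20%,
  potency CV ~20%, activity noise ~2%).

TBIL is drawn lognormally (median 12 umol/L, CV 30% — a stand-in, since
no cohort distribution is published) and acts on `v2` with exponent 0.5
by default so covariate-search tests have signal. The comparator arm uses
a one-compartment profile with a ~9 h half-life; only the NCA and PD
stages consume it. GLP-1 pulses (triangular 1 h rise, exponential decay
with 0.5 h half-life, scaled by `1 + k * inhibition/100`) and the OGTT
curves (gamma-shaped excursions scaled by an arm-level multiplier) are
phenomenological stand-ins: their job is to exercise the PD metrics with
realistic shapes, not to claim incretin physiology. Passing tests
demonstrate internal consistency of the pipeline under this generative
model — they cannot certify behaviour on features the generator lacks
(dropout, nonlinear absorption, assay drift, effect-compartment
hysteresis).

# Numerical choices and degenerate inputs

* Trapezoid integration errors on unsorted times; missing interior values
  are skipped with a warning.
* Terminal-slope fits need >= 3 positive post-Tmax concentrations; flat
  profiles return a typed "not estimable" result rather than zero.
* Ties for Cmax/Tmax resolve to the earliest time.
* Residual variances are floored at 1e-12 inside the likelihood;
  structural-model rate collisions are nudged by one part in 1e8.
* A subject with no observations contributes zero to the OFV and sits at
  the prior mode of its random effects.
* Bootstrap replicates re-key resampled subjects so duplicates stay
  distinct; a one-subject cohort yields zero-width intervals by
  construction.

# Problem sizes used in the tests

The test-suite harnesses run at deliberately moderated sizes chosen to
estimate their operating characteristics stably: parameter recovery uses
20 replicate 32-subject trials; the covariate-search power study uses 20
replicates of a 64-subject two-arm design with a thinned 14-sample
schedule and fitted variability on `cl` and `v2` only; bootstrap coverage uses
10 outer replicates of B = 200 on a reduced one-compartment model, which
exercises the identical resampling machinery at a fraction of the cost;
the VPC self-consistency check uses 200 simulations. The full-size
settings (B = 1000, 1000 VPC simulations) remain the defaults of the
exported functions.

# Known limitations

* The Laplace/Gauss-Newton OFV is an approximation for strongly nonlinear
  random effects; no SAEM or adaptive quadrature alternative is provided.
* Omega is diagonal; no inter-occasion variability.
* The comparator arm has no population model of its own.
* The generator does not reproduce the published terminal half-life (see
  the calibration notes above) and carries no adherence, dropout or
  mechanistic glucose-insulin physiology.
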