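---
title: "Methods: population PK/PD and clinical-outcome modelling of inhaled budesonide/formoterol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK/PD and clinical-outcome modelling of inhaled budesonide/formoterol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pkpdco)
```

## The model

`pkpdco` implements a population pharmacokinetic / pharmacodynamic /
clinical-outcome (PK/PD/CO) model for the fixed-dose budesonide/formoterol
combination inhaler (160/4.5 ug per puff) in adults with moderate asthma,
together with the machinery needed to estimate it, evaluate it, and use it
for dose-regimen simulation.

### Pharmacokinetics

Each inhaled dose is split between two absorption depots: a fraction FR
deposits in the lung and is absorbed with first-order rate $k_{a,lung}$,
while the swallowed remainder $1-FR$ enters the gut ($k_{a,gut}$).
Disposition is linear: one compartment for formoterol, two for budesonide
(model selection among one/two/three-compartment variants is exposed via
`compare_structures()`). Because the system is linear, plasma and lung
profiles have closed forms by superposition over dose events
(`pk_profile()`); `solve_individual()` offers the equivalent adaptive-ODE
route (`deSolve::lsoda`, rtol 1e-8, atol 1e-10, dose events as integration
restarts), and the two agree to a relative error below 1e-6 (tested).

### Lung concentration driver and units

The PD effects are driven by the concentration in the lung compartment:
the lung amount divided by a typical lung volume of 1.1 L. Internal
amounts are micrograms and volumes litres, so the native concentration
scale is ug/L. Budesonide concentrations are reported in ng/mL (identical
to ug/L) and formoterol in pg/mL (1 ug/L = 1000 pg/mL); the potency
parameters (IC50 = 0.025 ng/mL, EC50 = 0.081 pg/mL) and the assay LLOQs
(0.1 ng/mL, 1 pg/mL) are expressed on those scales, so no further
conversion happens at the point of comparison. The conversion factors are
centralized (`conc_unit_factor()`) and tested. A 320 ug budesonide
administration puts 121.6 ug in the lung, i.e. an initial lung
concentration of about 110.5 ng/mL versus an IC50 of 0.025 ng/mL; a 9 ug
formoterol administration yields about 3150 pg/mL versus an EC50 of
0.081 pg/mL. Both drugs therefore saturate their effect at the moment of
dosing, and the effect duration is governed by how long the declining lung
concentration stays above the C50 — this is what makes 1 puff b.i.d.
nearly as effective as 2 puffs b.i.d. in the simulations, since halving
the dose shifts the lung concentration curve down by only one doubling
while the decay rate ($k_{a,lung}$ around 15-20/h) is unchanged.

### Pharmacodynamics

Both biomarkers follow indirect-response (turnover) models with production
rate $k_{in}$ and loss rate $k_{out}$, and baseline stationarity
$k_{in} = k_{out} \cdot BASE$ built in:

* sputum eosinophil cationic protein (ECP, ng/mL), production *inhibited*
  by lung budesonide:
  $dR/dt = k_{in}(1 - I_{max} C/(IC_{50}+C)) - k_{out} R$;
* FEV1 (% predicted), production *stimulated* by lung formoterol:
  $dR/dt = k_{in}(1 + E_{max} C/(EC_{50}+C)) - k_{out} R$.

$I_{max}$ and $E_{max}$ default to 1 (full effect). No published value
exists for either; 1.0 is the standard full-effect convention and, with
it, the simulated 12-week control-status distribution reproduces the
published three-regimen table within a few percentage points, which we
treat as the operative justification. Both are configurable fields of
`turnover_params()`.

### Clinical outcome

The Asthma Control Test (ACT, instrument range 5-25) follows a symptomatic
disease-progression model: the score declines from its baseline at the
natural rate $\alpha$ while reversible biomarker changes add offsets,

$$ACT(t) = BASE_{ACT} - \alpha t + \beta_1 (BASE_{ECP} - R_{ECP}(t))
  + \beta_2 (R_{FEV1}(t) - BASE_{FEV1}).$$

All rate constants in the model are per hour, and we read $\alpha$ =
0.00083 on that same scale (a drift of about 1.67 points over the 12-week
horizon), consistent with every other rate in the parameter table. The
equation is left unbounded by default; clipping to the instrument range
[5, 25] is available via `co_params(clip = TRUE)` but is not part of the
published model, so it is off. Scores classify as well-controlled
(>= 20), partially controlled (15-19) and uncontrolled (< 15)
(`classify_act()`).

## Stochastic layers

Inter-individual variability is exponential, $P_i = TV \cdot e^{\eta}$,
$\eta \sim N(0, \omega^2)$, with the reported "CV%" interpreted directly
as $100\,\omega$ (the common pharmacometric reporting); the budesonide
deposition fraction uses logit-scale variability so sampled fractions
respect $0 < FR < 1$. Residual error is proportional for the two
concentrations and the two biomarkers (their magnitudes are reported as
percentages) and additive for ACT (SD 2.32 score units). Negative
simulated concentrations are floored at zero before the LLOQ check, and
concentrations below the LLOQ are flagged BLQ. Inter-occasion variability
is not included (none is reported for the final model); the covariate hook
(`covariate_model()`) supports linear, power, exponential and categorical
relations on any structural parameter.

## Trial simulation

`simulate_trial()` reuses the same virtual population (identical $\eta$
draws under one seed) across regimens, which is what makes week-0 rows
identical across scenarios and enables paired comparisons; ACT residual
error is drawn independently at each evaluation week. Week-0 evaluation is
pre-first-dose. Dosing clock times are 0 h and 12 h (b.i.d.) or 0 h every
24 h (q.d.); a multi-puff administration is one combined dose event.
As-needed extra dosing and rescue-medication use are not simulated.

The cohort simulator (`simulate_pd_cohort()`) avoids per-subject ODE
integration: between dose events the lung amount is exactly
mono-exponential, the integral of the saturable effect term has the closed
form $\int C/(C_{50}+C)\,dt = \log((C_{50}+C_1)/(C_{50}+C_2))/k_a$, and
each scalar turnover state (linear in $R$) advances by an exponential
integrator using the exact interval average of its forcing. Short
sub-steps (0.02 to 6 h) after each dose resolve the absorption transient.
Against the full adaptive ODE solution this is accurate to about 1e-4
relative (tested) and simulates 1000 subjects for 12 weeks in well under a
second.

## Estimation

`focei_ofv()` computes $-2\log$ of an approximate marginal likelihood by
the Laplace method around each subject's empirical-Bayes mode, with the
proportional residual variance evaluated at the conditional prediction
(first-order-conditional-with-interaction behaviour). No claim of
numerical equality with any existing NLME implementation is made; instead
the objective is validated against an adaptive-quadrature oracle on a
one-subject toy (agreement below 0.01) and by parameter-recovery
simulation at the trial's own design. With all IIV zero the objective
reduces to the exact Gaussian likelihood. Inner mode searches always start
from zero so that the objective is a deterministic function of the
population parameters — a requirement for the outer finite-difference
gradients. `fit_population()` optimizes positive parameters on the log
scale (covariate coefficients untransformed), supports multi-start
jittering, reports standard errors from the inverse numerical Hessian
(delta method back to the natural scale), and exposes the sequential
workflow (fit PK, fix, fit PK/PD, fix, fit PK/PD/CO) through its `fixed`
argument. `nlminb` terminations with "false/singular convergence" are
treated as soft convergence (the message is kept in the result): they
routinely reflect finite-difference noise rather than a genuinely
unconverged fit.

### BLQ handling

Censored concentrations are excluded from the likelihood by default (M1).
For budesonide (about 17% BLQ under the trial design) M1 is adequate, but
for formoterol, whose concentrations fall below the 1 pg/mL limit within
about 2 h so that roughly 40% of scheduled samples are censored, M1
induces a severe downward bias (about -40% on CL in our recovery
simulations). `pk_fit_model(blq = "M3")` therefore offers the
censored-likelihood method — BLQ records contribute
$\Phi((LLOQ - f)/\sigma_f)$ — and the recovery analyses use it for both
drugs. With M3, and the absorption parameters and variance components held
at their known values (mirroring the sequential fixing workflow), median
recovery bias of CL and Vc is within 15% for both drugs at the 53-subject
design.

### Model comparison

`lrt()` refers OFV differences to chi-square (3.84 for p < 0.05, 6.64 for
p < 0.01 at one df). `scm()` runs greedy forward inclusion (3.84) then
backward elimination (retention requires 6.64 on removal) with a full
audit trace. `compare_structures()` compares one- versus two-compartment
disposition at the chi-square criterion for its two extra parameters
(5.99 at df 2) — the generic single-df 3.84 rule would be too lenient for
a two-parameter addition — preferring the simpler model on ties or fit
failure.

## Diagnostics

* `vpc()` bins by nominal (scheduled) sampling time — the trial has fixed
  schedules, so data-driven binning would only blur the design — computes
  observed 5th/50th/95th percentiles, and builds simulated percentile
  bands across replicates; empty bins merge into a neighbour with a
  message. Both interpretations of "simulation in 1000 subjects"
  (replicates of the design, or one large cohort) are available to the
  caller through the `simulate` closure it receives.
* `bootstrap_fit()` resamples subjects with replacement and reports
  5th-95th percentile intervals. The default "linearized" mode resamples
  per-subject score contributions around the estimate with a one-step
  Newton update per replicate (fast, deterministic given the seed); the
  "refit" mode re-estimates each replicate at a reduced iteration budget
  and counts failures.
* `nca()` computes Cmax/Tmax by direct lookup and AUClast by the linear
  trapezoid to the last quantifiable point; leading/trailing BLQ points
  are dropped and embedded BLQ treated as missing (no zero substitution).

## Synthetic data

`generate_trial()` emulates the trial that produced the model: 53
subjects, 2 puffs b.i.d. for 12 weeks, rich PK sampling on Days 1 and 7
(0, 10, 20, 30, 45 min; 1-7, 9, 11 h) plus Day 3-5 troughs (taken 12 h
after the preceding evening dose), FEV1 at weeks -2 to 12, sputum ECP at
the lung-function visits, ACT at weeks 0-12, demographics matching the
study table, and LLOQ censoring. The week -2 run-in visit is generated at
the subject's own baseline with residual error only (the run-in's constant
budesonide maintenance dosing is not mechanistically simulated); a week -2
ECP row is available behind `runin_ecp = TRUE` since the sputum schedule
for the run-in visit is ambiguous. Covariates are generated independent of
the model parameters by default — the published analysis found no
significant covariate — with `generate_covariate_data()` to plant known
effects for stepwise-covariate-modelling studies. What the generator does
not emulate: as-needed dosing and rescue use, assay batch effects,
dropout, and adherence variation; passing tests therefore demonstrate
internal statistical consistency of the machinery, not robustness to
those real-data features.

## Problem sizes and numerical choices

Regimen simulations run 1000 subjects per scenario (matching the published
simulation size). The recovery study refits 5 replicate synthetic trials
per run at the full 53-subject design; stepwise-covariate calibration uses
200 null datasets of a small analytic toy model, which isolates the
likelihood-ratio behaviour from ODE cost. Sub-step offsets of the cohort
simulator (0.02/0.06/0.15/0.4/1/2.5/6 h) were chosen once to resolve the
2-4 minute absorption half-lives; integrator tolerances are rtol 1e-8 /
atol 1e-10. Ties in structural comparison go to the simpler model;
optimization starts are jittered with SD 0.2 on the estimation scale when
multi-start is requested.

## Known limitations

* The estimator is a Laplace approximation; for very sparse designs or
  extreme nonlinearity its small-sample behaviour (slightly conservative
  likelihood-ratio statistics, as the calibration tests show) differs
  from exact marginal likelihood.
* ECP parameters are intrinsically poorly determined — the biomarker's
  published variability is enormous (baseline IIV above 100%, residual
  about 72%) — and large uncertainties on its loss rate are expected
  behaviour, not a defect.
* The CO model inherits the published structure: a linear drift plus
  reversible offsets. It cannot represent floor/ceiling effects of the
  ACT instrument unless clipping is enabled, nor disease modification.
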