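---
title: "Individualised risk-based retinopathy screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualised risk-based retinopathy screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retscreen)
```

This vignette is the package's own account of the science it implements:
the disease and risk models, the trial and economic machinery built around
them, and the choices made where the underlying methodology left the design
open.

## The multi-state disease model

Retinopathy status is summarised by the graded state of both eyes:
`R0R0` (no retinopathy), `R1R0` (background retinopathy in one eye),
`R1R1` (background in both), and the absorbing state `SP` — screen-positive,
i.e. referable retinopathy (R2+), new proliferative disease (R3A),
referable maculopathy (M1), ungradable images or other significant eye
disease. Progression is a continuous-time Markov chain whose transition
intensities depend log-linearly on clinical risk factors:

$$q_{rs}(z) = \exp\{\log q^0_{rs} + \beta_{rs}\cdot(z - \bar z)\},$$

with $z$ the covariate vector (age, diabetes duration, HbA1c, systolic BP,
total cholesterol, prior-retinopathy indicator), centred at stored constants
$\bar z$ for optimisation conditioning and portability of the fitted object.
The default allowed-transition set is
`R0R0 <-> R1R0 <-> R1R1` plus an `SP` exit from every observable state:
background retinopathy is frequently observed to regress between screens,
so the observable states are connected in both directions (a "mixed" Markov
structure), while `SP` is absorbing; the direct `R0R0 -> SP` edge captures
maculopathy arising without prior background retinopathy. The structure is
an argument of `multistate_model()`, not a constant.

Horizon risks follow from the matrix exponential,
$P(t) = e^{Q(z)t}$, and the screen-positive risk over horizon $h$ is the
`[state, SP]` entry of $P(h)$. Because `SP` is absorbing the risk profile
$(r_6, r_{12}, r_{24})$ is non-decreasing in the horizon — a property the
test suite asserts over randomly generated models.

**Interval allocation.** The programme's rule is implemented in
`allocate_interval()`: the longest interval whose cumulative risk stays
*strictly below* the 2.5% threshold wins — low/24 months if $r_{24} < \tau$,
else medium/12 if $r_{12} < \tau$, else high/6. The underlying methodology
does not state how three horizon risks combine with a single threshold, nor
whether a risk exactly equal to the threshold qualifies for the longer
interval; this cascade with a strict inequality is the package's reading
(a tied risk gets the shorter, safer interval), and both the threshold and
the strictness are arguments.

## Fitting the engine to panel data

Screening produces interval-censored panel data: states observed at visit
times, with the path between visits unobserved. The likelihood of a
consecutive observation pair $(s_i, s_{i+1})$ separated by $\Delta t$ is the
matrix-exponential entry $P_{s_i s_{i+1}}(\Delta t; z_i)$, evaluated at the
covariates recorded at the interval's start; `fit_multistate_model()`
maximises the sum of the log entries by BFGS. Numerical choices:

* start at log-intensity −3 per month (≈ 0.05/month) and zero covariate
  effects; convergence by `optim`'s relative tolerance (default 1e-10);
* an allowed transition never observed as a consecutive pair is pinned to
  the floor `exp(-12)` per month with a warning and excluded from
  optimisation (its maximum-likelihood estimate sits on the boundary);
  if *no* transition is observed the whole model is returned at the floor;
* non-convergence is reported in the `convergence` field, never silently;
* standard errors come from the inverted numerical Hessian (Wald);
* the likelihood caches $e^{Q\Delta t}$ over unique (covariate row,
  interval) combinations and tabulates repeated `(from, to)` cells, so
  panels with banded covariates and a regular visit grid cost a handful of
  matrix exponentials per evaluation.

Covariate selection is forward by the corrected Akaike criterion
($AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)$, $n$ = participants), starting
from the covariate-free model and stopping when no addition improves AICc;
the full audit table is returned. Forward selection from the empty set is
the package's choice where the selection direction was unspecified.

Validation (`validate_model()`) reports per-horizon AUC (Mann–Whitney rank
form, ties at ½), sensitivity and specificity at the threshold, and a
concordance index for time-to-SP computed at the longest-horizon risk, with
optimism correction by refitting on bootstrap resamples and evaluating on
the original data. A horizon whose outcome cannot be ascertained on the
visit grid (e.g. 6-month outcomes under annual screens) yields an undefined
AUC, reported as `NA` rather than imputed.

## The synthetic cohort

`cohort_profile()` holds the generator's targets; its defaults are the
study conditions the package emulates — a large English community screening
population:

* baseline state mix 81.2% / 12.4% / 6.3% over R0R0 / R1R0 / R1R1;
* covariate marginals parameterised by median and IQR: log-normal for the
  right-skewed diabetes duration (median 7.0 y, IQR 4.2–11.0) and HbA1c
  (51 mmol/mol, 44–62), truncated normal for age (63.1 y, 54.9–70.7,
  range 14–101), systolic BP (130 mmHg, 122–138, range 84–213) and total
  cholesterol (4.0 mmol/l, 3.4–4.7, range 1.4–9.7); scale is IQR/1.349
  (log scale for the log-normal families);
* diabetes type 4.0% type 1 / 88.5% type 2 / 7.5% unknown;
* attendance probabilities by arm × baseline risk group (control
  0.773/0.817/0.857, individualised 0.723/0.822/0.851 for high/medium/low);
* withdrawal / loss to follow-up as a constant hazard equivalent to
  6%/annum — the conventional planning assumption for a 24-month screening
  trial — cancelling all later invitations;
* eight clinics with multinomial sizes as randomisation strata.

Covariates are sampled independently given these marginals: the dependence
structure among risk factors is not published, so none is invented. The
correlation that matters downstream — high-risk participants having longer
duration and higher HbA1c — is induced by the generating model's covariate
effects on progression, not hard-coded into the sampler. The
`prior_ret` indicator is set from the baseline state. Covariates are frozen
at baseline for path generation; real programmes refresh risk factors
between visits, but no update model is published, so time-updating is left
as an extension point rather than guessed.

`default_progression_model()` is the generating "truth": baseline
intensities (per month) 0.008 / 0.020 / 0.010 / 0.005 for the background
transitions and 0.0003 / 0.0012 / 0.004 for the SP exits, with positive
duration, HbA1c, blood-pressure, cholesterol and prior-retinopathy effects
on onset, worsening and SP exit. These values were chosen once so that the
implied 6/12/24-month risks put roughly 9% / 10% / 80% of a default cohort
into the high/medium/low groups — close to the emulated study's
8.7% / 9.3% / 81.9% — with R1R1 essentially always high-risk and R0R0
essentially always low-risk. Time is months throughout; the 90-day
attendance window is 3.0 months.

What the generator does **not** emulate: grading error and image-quality
pathways, ethnicity/smoking effects, treatment after STDR, seasonal
scheduling, and covariate drift. Passing tests therefore demonstrate that
the *analysis machinery* is correct under the stated generating assumptions,
not that the generator reproduces every feature of real screening data.

## The trial simulator

`randomise()` implements stratified permuted blocks (random block sizes 4/6
within clinic × adult stratum, 2 for under-16s), so arms are exactly
balanced within every completed block. `run_trial()` then:

* invites control participants at 12-month multiples and individualised
  participants at their allocated interval, reassessed by the engine from
  the observed state and covariates at every attended visit;
* draws attendance with the arm × baseline-group probability, and an actual
  visit time uniform in the 3-month window after the invitation;
* reads the observed state off the true path at the actual time
  (measurement = truth at the visit; no grading error is modelled);
* confirms a screen-positive observation as STDR with probability
  `stdr_fraction` (default 0.24, matching the observed ratio of confirmed
  STDR to screen-positive events pooled over both arms), after which the
  participant exits routine recall; false positives are re-entered, their
  trajectory restarting from the pre-absorption state at the visit time;
* re-invites non-attenders one interval after the missed invitation (one
  invitation per cycle);
* supports injectable wrong-interval protocol deviations for exercising the
  per-protocol / intention-to-treat split, and a calibration mode
  (`baseline_group_probs`) that draws baseline groups from a supplied mix
  instead of the engine — used when the simulation is pinned to an observed
  risk-group distribution.

`build_analysis_sets()` derives both analysis sets: per protocol excludes
deviations and pre-invitation withdrawals; intention to treat keeps every
randomised participant, counting unobserved outcomes as non-events. That
fill-in is deliberately crude and conservative — it penalises the low-risk
group, whose first invitation at 24 months leaves the most time to
withdraw — which is exactly why the multiple-imputation path exists: MI
under baseline covariates restores comparability, and the analysis drivers
report it alongside the complete-case results.

## Safety statistics

Single proportions get Wilson score intervals; differences get the Newcombe
square-and-add combination of the two Wilson intervals, without continuity
correction — the uncorrected variant is the one that reproduces the
published intervals exactly from the published counts, which is how the
choice between variants was settled. The normal quantile is kept at full
precision (1.959964); rounding to the printed precision happens only at
report formatting. Equivalence requires the CI strictly inside ±5%;
non-inferiority requires the lower bound strictly above −1.5%;
boundary-touching intervals establish neither (both margins and the
strictness are arguments).

Multiple imputation draws missing binary outcomes from a logistic model on
baseline characteristics fitted to complete cases, with the coefficient
vector redrawn from its approximate normal posterior per imputation
(proper MI), m = 20 by default — the emulated analysis does not state m,
and 20 keeps the Monte-Carlo error in the pooled variance small at this
scale. Rubin pooling uses total variance $W + (1+1/m)B$ and the standard
$(m-1)(1 + W/((1+1/m)B))^2$ degrees of freedom. Deterministic best/worst
fill rules are provided for sensitivity analyses.

## Health economics

Costs are £28.73 per attended and £12.73 per missed appointment (NHS), plus
£9.00 per attendance from the societal perspective (2019/2020 values), at
exact 2-decimal arithmetic. QALYs are the trapezoidal area under the
linearly interpolated utility index over the 2-year horizon (time in
years), truncating at the horizon and extrapolating flat when a series ends
early; no discounting over the 2-year horizon. Utilities are consumed as
already-valued indices — tariff and crosswalk machinery is out of scope —
and the synthetic generator produces baseline-correlated indices with mass
near full health (EQ-VAS generated on 0–100 and rescaled by /100; HUI3
floored at −0.36).

Incremental QALYs and costs come from least-squares regression on the arm
indicator (QALYs optionally adjusted for baseline utility), bootstrapped by
resampling participants with replacement *within arm* (preserving the
design) for 1000 iterations, with bias-corrected percentile intervals: the
BC variant without acceleration term, the minimal reading of
"bias-corrected", switchable in `bc_interval()`. A degenerate bootstrap
distribution collapses the interval onto the point estimate; single-arm
resamples are redrawn and counted. Across multiply imputed sets the cost
and QALY equations are estimated jointly by two-equation feasible-GLS
seemingly unrelated regression (coinciding with OLS under identical
regressors or diagonal error covariance — a tested identity) and the arm
coefficients pooled by Rubin's rules.

## Problem sizes and runtimes

The test suite and acceptance script run everything at the scale of the
emulated study where that is cheap (published-count statistics, the
n = 4321 calibrated trial replicates) and at reduced but statistically
adequate scale where fitting dominates: multi-state recovery uses panels of
2000 participants × 5 annual visits with 50 replicate refits; Newcombe
coverage uses 2000 simulated tables per scenario; bootstrap-CEA coverage
uses 1000-participant trials with 1000-iteration bootstraps. The analysis
drivers band duration (5-year) and HbA1c (10 mmol/mol) in the engine
development panel, as screening services do in risk tables, which also
keeps the interval-likelihood cache compact.

## Known limitations

* The deployed engine's coefficients were fitted to a confidential
  development dataset and are not public; the engine here is structurally
  faithful and fitted to synthetic panels, so its discrimination metrics
  (and any simulated attendance or cost figure) are calibration summaries,
  not reproductions of the published values.
* Independent covariate sampling understates real risk-factor correlation;
  risk-group covariate profiles emerge only through the progression model.
* Attendance is exchangeable Bernoulli given arm × baseline group; no
  habit formation, deprivation gradient or distance-to-clinic effect.
* The intention-to-treat non-event fill-in is a design choice exposed for
  sensitivity analysis, not a recommendation; use the imputation path for
  headline estimates.
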