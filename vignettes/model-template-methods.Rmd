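---
title: "The PBPK model template: structure, numerics, and timing experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PBPK model template: structure, numerics, and timing experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbpktemplate)
```

## The model

A physiologically based pharmacokinetic (PBPK) model tracks the mass of
a chemical in anatomically meaningful compartments connected by blood
flow.  This package implements a *template superstructure*: one maximal
whole-body model containing every compartment, exposure route,
metabolic pathway and representation option the family supports, from
which a chemical-specific model is obtained by switching features off.
Unused pathways carry zero rate parameters and deactivated compartments
carry zero blood flow, so their equations evaluate to zero without
changing the solution.

The superstructure integrates **53 state variables**:

* 17 compartment amounts (mg): arterial and venous blood, lung tissue,
  the gas-exchange region, fat, liver, kidney, richly and slowly
  perfused tissue, skin, stomach and intestine walls, stomach and
  intestine lumen, a closed exposure chamber, a dermal vehicle, and an
  injection depot;
* 9 cumulative-metabolism accumulators: four saturable
  (Michaelis-Menten) pathways (two hepatic, one pulmonary, one renal)
  and five first-order pathways (liver, lung, kidney, stomach,
  intestine);
* 13 cumulative intake/elimination accumulators (five intake routes,
  exhaled/urine/feces/chamber-loss elimination, three absorption
  tallies, and total metabolism);
* 14 AUC accumulators (mg·h/L) integrating compartment concentrations.

Alongside the states, **105 output variables** are computed
algebraically: compartment concentrations, venous-equilibrated tissue
concentrations, blood composites, air-phase concentrations, metabolism
and intake rates, mass-balance diagnostics, per-kg amounts, cumulative
dose fractions, time-weighted averages, and scaled-parameter echoes.  A
reduced map with **76 outputs** drops the echoes, dose fractions,
air-phase and blood-composite groups (about 25% fewer).

### Equations

All tissues are flow-limited: a tissue with blood flow $Q_i$, volume
$V_i$ and tissue:blood partition coefficient $P_i$ obeys

$$\frac{dA_i}{dt} = Q_i\left(C_{art} - \frac{C_i}{P_i}\right)
  - \text{metabolism}_i + \text{route inputs}_i,
  \qquad C_i = A_i / V_i .$$

Stomach and intestine wall effluent drains through the liver (portal
flow), and gastrointestinal absorption from the lumen enters the liver
directly (first pass).  Saturable metabolism acts on the
venous-equilibrated concentration $C_i/P_i$ with rate
$V_{max} c/(K_m + c)$; first-order metabolism is proportional to the
compartment amount ($k_f A$, units /h).

Gas exchange uses the classic equilibrium form: the pulmonary-venous
concentration is

$$C_{pv} = \frac{Q_C\,C_{ven} + Q_{alv}\,C_{inh}}
  {Q_C + Q_{alv}/P_{ba}},$$

with exhaled air at $C_{pv}/P_{ba}$.  Alternatively the gas-exchange
region can be carried as a state variable (`gas_exchange_mode =
"GE_STATE"`).  The venous and arterial blood pools can likewise be
carried as state variables (the default in the two shipped mappings) or
replaced by algebraic steady-state approximations (`blood_mode =
"SS_APPROX"`).  The lung is a parallel perfused compartment; removing
it also removes pulmonary metabolism, which for the dichloromethane
model means the no-lung variant omits a biologically relevant process
(this is inherent to the option, not a defect).

### Body weight and allometry

Exactly **28 quantities derive from body weight**: 11 compartment
volumes (∝ BW), 9 perfused-tissue flows plus cardiac output and
alveolar ventilation (∝ BW^0.75^), 4 saturable capacities (∝ BW^0.75^),
urinary clearance (∝ BW^0.75^), and skin surface area (∝ BW^0.667^).
First-order rate constants are per-hour rates applied to amounts and do
not rescale; this choice keeps the body-weight-dependent roster at
exactly 28 (an alternative convention scales them by BW^-0.25^, which
would enlarge the roster to 33).

Body weight itself is handled in one of three modes:
`INPUT_TABLE` (piecewise-linear interpolation of a time/BW table,
clamped at the ends, with all 28 dependents recomputed at every
derivative evaluation), `FIXED_DYNAMIC` (constant BW, dependents still
recomputed every call), and `FIXED_INIT` (dependents computed once per
simulation).  For a constant-valued table the three modes produce
identical trajectories; they differ only in where the work happens.

### Conditional sites

The template contains **32 two-way conditionals**: 4 in the INITIALIZE
section (evaluated once per simulation) and 28 in the DYNAMICS section
(evaluated at every step).  Each can be realized as a branch (the
compiled ternary operator) or as a multiplicative 0/1 switch
$s\,a + (1-s)\,b$.  For finite operands IEEE arithmetic guarantees
$1\cdot a + 0\cdot b = a$ exactly, so the two realizations produce
bit-identical trajectories — which is what makes the timing comparison
between them meaningful.

### Structural pruning

`prune_states()` eliminates states that the configuration makes
structurally inert: amounts and AUCs owned by deactivated compartments,
amounts replaced by a steady-state algebraic mode, and metabolism
accumulators of inactive pathways.  The 13 intake/elimination
accumulators are **never** pruned: exposure routes are properties of
the simulated scenario (an `exposure_schedule`), not of the model
structure, so their accumulators are not inert under any configuration.
For the dichloromethane mapping this removes 19 of 53 states (34
remain); for chloroform, 20 of 53 (33 remain).  Pruned and full
engines produce identical trajectories for the retained states: the
derivative expressions differ only by added exact zeros, and the
integrator's weighted max-norm error control is invariant to padding
the state vector with identically-zero components.

## Stand-alone models

Dedicated implementations of the dichloromethane (DCM) and chloroform
(CF) models are coded independently of the template (separate compiled
derivative, Jacobian and output routines): DCM with 21 states and 22
outputs, CF with 19 states and 26 outputs.  Both fix body weight at
initialization.  Their equations match the template's active equations
term-for-term, so template and stand-alone runs at tolerances 1e-10
agree to well below the 1e-6 acceptance threshold — the residual
discrepancy (~1e-10) is the two solvers' differing step sequences, not
formulation differences.  The state/output counts are the published
figures; the exact rosters behind them are this package's
reconstruction, pinned by tests.

## Exposure scenarios

Four canonical two-week (336 h) scenarios: (1) constant continuous
inhalation; (2) constant continuous oral delivery to the stomach lumen;
(3) periodic inhalation, 6 h/day, 5 days/week (10 windows); (4) oral
boluses 6×/day, 7 days/week (84 events).  Only the counts are part of
the scenario definitions; the clock anchors (windows 09:00–15:00,
boluses at 02:00, 06:00, …, 22:00) are package conventions chosen so
that every event lies inside the window — a 06:00-anchored 4-hourly
schedule would push the last bolus of day 14 to t = 338 h, outside it.
Boluses are instantaneous state jumps applied between integration
segments with a full integrator restart; dosed mass is mirrored into
the cumulative-intake accumulator at the same instant, which makes the
event-mass accounting exact rather than integrated.

Default dose levels used in examples and tests: 0.35 mg/L inhaled air
(≈100 ppm DCM), 50 mg/h continuous or 50 mg per bolus orally — typical
occupational/toxicological magnitudes; the timing and equivalence
properties are insensitive to them.

## Numerics

No stiff ODE library is assumed; the integrators are part of the
package (compiled, Rcpp):

* **`"rosenbrock"`** (default at ordinary tolerances): a 4-stage
  linearly implicit Rosenbrock method of order 3(2), L-stable and
  stiffly accurate, with an embedded error estimator that vanishes in
  the stiff limit.  It uses an **analytic Jacobian**, hand-coded for
  the template and both stand-alone models.  This matters beyond
  speed: Rosenbrock methods inject the Jacobian directly into the
  update, so a finite-difference Jacobian would leak truncation error
  into conserved quantities; with the exact Jacobian, linear mass
  conservation holds to round-off.
* **`"dp5"`**: an explicit Dormand–Prince 5(4) pair with FSAL.  The
  fastest template eigenvalue (cardiac output over arterial volume,
  ~240/h) limits its stable step to ~0.014 h, so it is the method of
  choice only when tolerances are tight enough that accuracy, not
  stability, binds.
* **`"auto"`** (default): `dp5` for rtol ≤ 1e-8, `rosenbrock`
  otherwise.

Both methods use a weighted max-norm error control
$\max_i |e_i|/(atol + rtol\,|y_i|)$ — deliberately not an RMS norm, so
that the step-size sequence is unaffected by inert zero states and
pruned-vs-full comparisons are exact.  Both are Runge-Kutta-type
schemes, which preserve linear first integrals; the mass-balance
diagnostic (total input − in-body − eliminated) therefore stays at
accumulated round-off (~1e-14 relative) at *any* tolerance, and the
1e-8 acceptance bound tests structural correctness of the equations,
not solver accuracy.  Solver defaults are rtol = atol = 1e-6;
equivalence checks override to 1e-10/1e-12 so formulation differences
dominate numerical noise.

Fixed nominal volumes close dimensional gaps for regions without a
physiological volume fraction: gas-exchange region 0.3 L, lumen
segments 1 L, dermal vehicle 1 L, depot 1 L, chamber 1000 L; depot
release 0.1/h and chamber loss 0.01/h are package constants.  These
regions are inactive in both shipped mappings and exist to exercise
the superstructure and its pruning.

## The virtual population

`sample_population()` emulates a Monte-Carlo human sample.  The
published analyses drew from distributions that are not printed in the
source material, so the defaults are a documented stand-in that
preserves the statistical shape such analyses require: body weight
lognormal (median 70 kg, CV 20%), fractional volumes and flows normal
(CV 20%), all truncated at ±3 SD.  The slowly perfused compartment is
the *balance compartment*: its volume fraction is the remainder up to
the reference total body fraction (0.88), so the sum constraint holds
by construction and the sampled marginal means stay unbiased —
whole-subject rejection sampling against the sum constraint would bias
the volume means by roughly a percent.  Flow fractions are renormalized
to sum to exactly 1 per subject, which leaves their post-normalization
means with an O(CV²) bias; the 3-standard-error calibration therefore
applies to body weight and the volume fractions, which are the sampled
truncated distributions.  Per-subject RNG substreams (seeded by
subject index) make the first k subjects identical for any population
size, so the 1 k subset used for periodic scenarios is stable.
Chemical (metabolic) parameters stay at their reference values in the
default population; subjects are physiology records.

What a green population test establishes: the generator is seeded,
fast, constraint-satisfying, and calibrated to its own specification.
It does not establish human realism of the variability model — the
timing experiments are insensitive to the exact hyperparameters, which
is why a documented stand-in is adequate here.

## Timing experiments

`run_experiment()` reproduces the eight implementation-choice
comparisons: (1) template vs stand-alone; (2) ternary conditionals vs
multiplicative switches; (3) 50/100/500 requested output points;
(4) 105 vs 76 outputs; (5) the three body-weight modes; (6) full vs
pruned roster; (7) blood steady-state vs state variables; (8) the
lung/gas-exchange triple.  Measurements are CPU (process) time, not
wall clock; the timed span covers exactly the per-subject work
(parameter update, event setup, background-exposure check, solve,
result collection), with one-time setup excluded, and the solve-only
sub-span recorded separately.  The repetition protocol defaults to 10
repetitions; pairs are compared with Welch's unequal-variance t-test at
p < 0.05 (the published analysis does not name its test; Welch is this
package's choice).

Absolute seconds and percentage savings are hardware-dependent and are
not reproduced; the suite asserts *directional* orderings only
(pruned < full, init-time parameters < table-driven body weight,
stand-alone < template), as one-sided mean comparisons at batch 100 and
10 repetitions.  These orderings are asserted under the explicit
integrator: the contrasts at stake are per-derivative-call work
(recomputing 28 body-weight dependents, evaluating extra state
equations), and the explicit method is the regime where derivative
calls dominate the budget.  Under the stiff method the LU
factorization (which still scales as the cube of the state count, so
the pruning and stand-alone orderings persist) masks the body-weight
contrast below timer resolution — itself a finding about
implementation choices: how much an option costs depends on what the
integrator spends its time on.

## Known limitations

* The state/output/conditional rosters are reconstructions constrained
  by the published counts; the archived template's exact identities may
  differ.
* Flow-limited perfusion only; no diffusion-limited option.
* The lung is a parallel perfused compartment rather than in series
  with the gas-exchange region.
* No correlated population sampling; no rodent parameterizations; no
  parallel batch execution (deliberately, matching the published
  protocol).
* Closed-chamber and depot routes are engine features exercised
  structurally (pruning, conditionals) but not by any shipped scenario.
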