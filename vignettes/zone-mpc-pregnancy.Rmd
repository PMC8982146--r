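---
title: "Zone-MPC automated insulin delivery for pregnancy: models, tuning, and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zone-MPC automated insulin delivery for pregnancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`apzone` is a closed-loop simulation toolkit for automated insulin delivery
(AID) in type 1 diabetes, built around a zone model-predictive controller
(zone-MPC) tuned to the tight glycemic targets of pregnancy (63--140 mg/dL,
versus the standard 70--180 mg/dL). This vignette describes the models the
package implements, the parameters that matter and why their defaults are
what they are, and what the verification suite does and does not demonstrate.

## The closed loop

A run of `run_closed_loop()` couples four components at a 5-minute sampling
period over 25 simulated hours, the first hour open loop:

1. **Virtual patient (plant).** A deterministic glucose--insulin--meal ODE.
2. **CGM sensor.** Plasma glucose plus first-order autocorrelated noise,
   clipped to the reportable range 39--400 mg/dL.
3. **Zone-MPC controller.** A convex receding-horizon program that commands
   a per-step insulin micro-dose relative to the programmed basal.
4. **Bolus calculator.** Feed-forward meal boluses with a conditional,
   capped correction component; meals are always announced accurately.

## The metabolic plant

The plant follows the standard compartmental structure used by
research-grade T1D simulators. Plasma and tissue glucose masses
$G_p, G_t$ (mg/kg) exchange at rates $k_1, k_2$; endogenous glucose
production is the clamped linear form

$$EGP = \max\{0,\; k_{p1} - k_{p2} G_p - k_{p3} X^L + \xi X^H\},$$

insulin-dependent utilization is Michaelis--Menten with an insulin-action
gain,

$$U_{id} = \left[V_{m0} + V_{mx} X (1 + r_1\,\mathrm{risk})\right]
  \frac{G_t}{K_{m0} + G_t},$$

and the model is completed by constant insulin-independent utilization,
threshold-linear renal excretion above about 180 mg/dL, a two-compartment
subcutaneous insulin depot feeding plasma insulin, first-order insulin-action
states $X$ (utilization) and $X^L$ (liver), and a three-compartment gut chain
with unit bioavailability so that ingested carbohydrate mass is conserved
exactly. The insulin-action states are *deviations* from the subject's basal
insulin level; $k_{p1}$ absorbs the basal offset, which is algebraically
identical to the textbook form. The glucagon branch $\xi X^H$ is present in
the code but zero by default (no scenario doses glucagon), and the risk
amplification $r_1$ defaults to 0; the one-sided hypoglycemia risk function
(zero at and above ~112.5 mg/dL, a log-power curve below) is available via
`risk_value()` and is configurable.

**Insulin sensitivity scenarios** scale $V_{mx}$ (peripheral) and $k_{p3}$
(hepatic) multiplicatively via `apply_sensitivity_modifiers()`: this is the
package's model of pregnancy-induced insulin resistance (late pregnancy:
-67%) or heightened sensitivity (early pregnancy / hypoglycemia-prone
settings: +25%). Because both actions are deviations from basal insulin,
scaling them leaves the nominal fasting equilibrium untouched and changes
only the response to insulin excursions -- which is exactly what the basal
titration footnote of the protocol requires.

### Parameter defaults and the synthetic cohort

No published subject parameter sets are bundled: the cohort is synthetic by
construction. `generate_cohort()` draws log-normal multiplicative jitter
(CVs of 10--20%) around a single set of defaults and then *completes* every
subject with `make_subject()`, which derives the basal plasma insulin from
the subject's nominal basal rate and solves $k_{p1}$ so the plant is exactly
at steady state at the subject's nominal fasting glucose (drawn around
120 mg/dL, the typical open-loop fasting level under a native basal). The
defaults were chosen once for physiological realism of the *responses*, not
of individual rate constants:

* a 1 U subcutaneous bolus lowers glucose by roughly $1800/\mathrm{TDI}$
  mg/dL (the correction-factor rule), with action peaking near one hour, as
  for rapid-acting analogs;
* a 40 g meal produces a 60--80 mg/dL excursion peaking about an hour after
  intake when covered by a carbohydrate-ratio-matched bolus;
* basal titration from 0--5 U/h spans fasting equilibria from roughly
  210 down to 60 mg/dL, so the protocol's `b(90)` and `b(170)` titrations
  bracket for every subject (draws that fail either titration are rejected
  and redrawn deterministically).

Treatment profiles use the 500 rule (CR $= 500/$TDI) and the 1800 rule
(CF $= 1800/$TDI), with TDI made self-consistent with three 40 g meals per
day (TDI $= 24\beta + 120/\mathrm{CR}$, giving TDI $\approx 31.6\,\beta$).

What the generator does **not** emulate: diurnal variation of insulin
sensitivity and treatment parameters, gastric-emptying nonlinearity,
meal-size misestimation, exercise, stress, sensor dropout or drift. Passing
tests therefore demonstrate correctness of the algorithmic machinery and
qualitative robustness across the scenario grid, not clinical performance on
real patients or on any licensed simulator cohort.

## The controller

### Prediction model and observer

The controller predicts with a deliberately simple third-order discrete
transfer model from differential insulin (U per 5-min step, relative to
basal) to differential glucose (mg/dL relative to the reference $G_{ref}$),
in companion form over the state
$x(k) = (G(k{+}2), G(k{+}1), G(k)) - G_{ref}$. Its poles are fixed at
$(0.96, 0.93, 0.93)$ and its steady-state gain at $-1800/\mathrm{TDI}$: the
gain encodes the per-unit correction rule, and the pole speed was chosen so
that a meaningful fraction of the insulin response is visible inside the
45-minute prediction horizon -- with much slower poles the optimizer sees
almost no effect of insulin within the horizon and neither suspends in
hypoglycemia nor saturates in hyperglycemia. A Luenberger observer with
poles placed at 0.5 (Ackermann) filters the CGM signal.

### Cost and constraints

One step solves, over the plan $u(0..N_u{-}1)$ with $N_u = 5$, $N_p = 9$:

$$J = \underbrace{\sum_j \|G_{ZL}-G_j\|_\gamma^2 + Q\,\|G_j-G_{ZH}\|_\gamma^2}_{J_1}
 + \underbrace{\hat D \sum_j \|\tfrac{G_j - G_{j-2}}{10}\|_\gamma^2}_{J_2}
 + \underbrace{\sum_m R_+\|u_m\|_\gamma^2 + R_-\|{-u_m}\|_\gamma^2}_{J_3},$$

with $\|x\|_\gamma = \max(0, x)$, subject to total delivery
$u + u_{basal} \in [0, \min(u_{UB}, u_{IOB})]$ per step and zero input
beyond the control horizon. Conventions chosen where the published
description leaves room:

* the velocity term penalizes only *rising* glucose (the one-sided
  seminorm), matching its stated purpose;
* $\hat D$ (default multiplier $D = 10$) and the above-zone weight
  $Q$ are evaluated once per solve at the *current* measured glucose,
  velocity and IOB, which keeps the stage cost convex in the plan;
* the $Q$ table is a documented step function: weight 500 when the current
  velocity magnitude is at most 1 mg/dL/min **and** the insulin on board is
  below $\mathrm{IOB}_{required} = (G - G_{ref})/CF$ -- persistent
  hyperglycemia that standing insulin will not fix -- and 1 otherwise. It is
  deliberately identical across all three presets;
* the day window for both the zone schedule and the 4$\times$-basal pump
  limit is 06:00--22:00 (wider zones begin at 6 AM; outside the window the
  per-step cap is 1 U).

The cost is convex, piecewise quadratic and $C^1$; `mpc_solve()` minimizes
it with a deterministic two-metric projected Newton iteration (compiled),
with the strictly convex $J_3$ term guaranteeing a unique minimizer, so no
tie-breaking is ever needed. The test suite certifies the solver against
exhaustive plan enumeration (0.01 U global grid with $5\times10^{-4}$ U local
refinement -- the refinement is required because the 6500-weight curvature
makes a bare 0.01 U grid too coarse to certify $10^{-4}$ relative cost
agreement).

A subtlety of the one-sided velocity term: when glucose sits *below* the
reference, the free response creeps upward toward it, so the mathematical
optimum is not exactly basal but within $10^{-6}$ U of it; at or above the
reference, zero-deviation optimality is exact. The tests assert both
regimes.

### Insulin-on-board accounting

IOB sums user boluses under a fixed-length curve ($\lambda$: 4 h baseline,
3 h pregnancy) and controller micro-doses *relative to basal* under a
glucose-dependent curve ($\mu$: 6 h below 120 mg/dL, 4 h in 120--180, 2 h at
or above 180 -- shorter memory when hyperglycemic, so the controller is
freed to act sooner). Decay curves default to linear; a curvilinear
bi-exponential shape is available and satisfies the same boundary and
monotonicity invariants. Because micro-doses can be negative (suspensions),
total IOB can be negative; the user-bolus component cannot.

### Presets

Three presets ship as YAML under `inst/extdata/presets/` and via
`controller_preset()`:

| element | baseline | zone-adjusted | pregnancy |
|---|---|---|---|
| day zone (mg/dL) | 90--120 | 80--110 | 80--110 |
| night zone (mg/dL) | 100--120 | 80--100 | 80--100 |
| $G_{ref}$ (mg/dL) | 110 | 90 | 90 |
| velocity band (mg/dL) | 140--180 | 140--180 | 120--180 |
| $\lambda$ (h) | 4 | 4 | 3 |
| correction threshold $\tau_c$ (mg/dL) | 150 | 150 | 100 |
| correction target (mg/dL) | 150 | 150 | 90 |
| full-bolus threshold $G^m$ (mg/dL) | 120 | 120 | 70 |

$R_+ = 6500$, $R_- = 100$, $\alpha = 0.8$, the 2 U correction cap, the
120-min inter-bolus lockout, and the $Q$/$\mu$ shaping are common to all
three. The full-bolus branch uses the strict inequality $G > G^m$, so a
reading exactly at the threshold takes the reduced branch.

## Scenarios and metrics conventions

The 13-scenario verification grid (`scenario_ids()`, YAML under
`inst/extdata/scenarios/`) crosses insulin-sensitivity changes, initial
glucose, basal titration modes (`b(90)`, `b(170)`, scalings), carbohydrate
ratio / correction factor mis-adjustments, and meal-bolus timing. Encoding
choices made where the protocol table leaves detail open:

* the simulation clock starts at 07:00, so the 25-hour window holds the
  08:00/13:00/19:00 meals and a complete next-morning 06:00--07:00 fasting
  window;
* `+10%` treatment scalings multiply CR and CF (weakening dosing), per the
  protocol's sign convention; scenario C.2 is encoded exactly as tabulated
  (CR nominal, CF -33%, basal +50%, advance bolusing);
* basal titration always runs on the subject's *default* physiology
  (12-hour warm-up, then a 2-hour fasting read, bisection on [0, 5] U/h to
  within 2 mg/dL); scenario sensitivity modifiers are applied afterwards;
* an unspecified initial glucose means the open-loop equilibrium of the
  scenario's (modified) plant under the scenario's basal.

Metrics are CGM-based over the 24-hour closed-loop window. Range bins are
inclusive at both endpoints with strict below/above, so the three bins
partition exactly. The postprandial window is $(t_{meal}, t_{meal}+120]$;
a window truncated by the end of a run is computed over the available
samples and flagged. Fasting glucose is the mean CGM over 06:00--07:00 of
day 2. TDI is all commanded insulin in the closed-loop window plus user
boluses (including an advance bolus given just before loop closure).
`paired_compare()` is the classical two-sided paired t test and refuses
zero-variance differences rather than fabricating a p value.

## Numerical choices

* **Integrator**: explicit fixed-step RK4 at 1-minute internal steps inside
  5-minute control steps; the dynamics are non-stiff at these rates and a
  fixed step makes every run bit-reproducible. Halving the step changes a
  25-hour endpoint by well under 0.5 mg/dL (tested). Compartment masses are
  clamped at zero after each internal step.
* **Equilibria** are found by nested scalar root-finding (`uniroot`) on the
  reduced steady-state equations, not by long simulation.
* **Seeding**: every run's randomness (CGM noise, cohort draws) flows from
  explicit integer seeds; the experiment grid derives one seed per cell
  from the master seed with a fixed integer recurrence, so reruns are
  bit-identical and cells are independent of loop order.
* **YAML round trips** write numerics at 22 significant digits so that
  subject, preset and scenario files reload bit-exactly.

## Problem sizes used by the verification suite

The test suite runs the full directional comparison at 10 synthetic
subjects $\times$ 11 non-extreme scenarios $\times$ 3 presets $\times$ 10
CGM-noise replicates (3,300 closed-loop days), checks the solver against
enumeration on 100 random states at a reduced horizon ($N_p = 4$,
$N_u = 2$), and exercises every safety bound on full-length runs. These
sizes are the package's chosen verification protocol; the same machinery
scales to larger grids via `run_experiment()` and the `apzone` command-line
front-end.

## Known limitations

* The plant is a reduced academic model with synthetic parameters: results
  support algorithm verification, not clinical claims, and the absolute
  time-in-range numbers depend on the cohort generator's realism choices.
* Hypoglycemia exposure in the synthetic cohort is milder than what a
  licensed simulator cohort exhibits in extreme scenarios; the suite
  asserts directions and safety properties, not hypoglycemia magnitudes.
* Prediction-model constants (poles, observer gain) and the $Q$/$\mu$/IOB
  curve shapes are documented package defaults standing in for values that
  live in controller-lineage references; all of them are configurable.
* No diurnal sensitivity, exercise, unannounced meals, rescue
  carbohydrates, or glucagon delivery.
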