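---
title: "Modeling HRQoL dynamics around CAR T-cell therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling HRQoL dynamics around CAR T-cell therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartqol)
```

## The model

`cartqol` simulates the health-related quality of life (HRQoL) of a single
cancer patient from the approval of CAR T-cell therapy (`t = 0`) through a
fixed post-infusion horizon. The infusion happens at `t = D` days; all
outputs also carry time-since-infusion `t - D` so trajectories can be read
on the clinical "time zero = infusion" axis.

Five stocks, all normalized to `[0, 1]` except the CAR T-cell level, evolve
by coupled ordinary differential equations:

* **Tumor burden** `B`: logistic net growth with a stage-acceleration factor
  (more advanced disease progresses faster — a reinforcing loop), minus a
  kill term `k * min(P/Pref_eff, 1) * C * B` in which low physical
  well-being degrades treatment efficacy (a balancing loop).
* **CAR T-cell level** `C`: zero before infusion; afterwards it expands in
  proportion to available tumor antigen `B/(B + hB)` and the same physical
  gate, and contracts at rate `delta`. At the shipped calibration the
  contraction term dominates, so treatment intensity is set mainly by the
  infused bolus `Cdose * eta` and decays over weeks; the expansion term
  contributes a modest burden-dependent prolongation.
* **Side-effect severity** `S` (cytokine-release-syndrome-like toxicity):
  generated by the kill flux `C * B`, amplified by physical frailty
  `1 + mu * (1 - P)`, saturating at 1, and cleared at the management rate
  `m` (the care team's balancing loop).
* **Physical well-being** `P`: first-order goal seeking toward a
  homeostatic target `clamp(1 - wB*B - wS*S + wA*Aphys)`, where physical
  activity `Aphys = P * (omega + (1-omega)*M)` closes the reinforcing
  activity loops with psychological well-being.
* **Psychological well-being** `M`: rate-limited adaptation toward
  `clamp(mbase + cact*Apsy - cB*B - cS*S)`. The adaptation rate is scaled
  by the coping capacity `kappa`, the fraction of a reference daily time
  budget actually free after non-discretionary hours, impairment-inflated
  obligations, and social support:
  `Teff = max(Toblig*(1 + iota*(1-PS)) - Uavail, 0)`,
  `kappa = min((24 - Tbasic - Teff)/Tcope_ref, 1)`.
  This realizes hedonic adaptation as a resource-limited process: a sicker
  patient has less daily slack in which to adjust psychologically.

HRQoL is the auxiliary `Q = wQ*P + (1 - wQ)*M` (reported as 0 after death),
and performance status is identified with physical well-being (`PS = P`):
the two are separately named clinical concepts but enter the model through
a single causal arrow, and a monotone transform between them would add
parameters without changing behavior.

Two discrete events are resolved exactly at step boundaries. At `t = D`
eligibility is reassessed once: if `PS >= PSmin` the patient receives
`C <- C + Cdose * eta` with `eta = clamp(1 - lambdaB*B) * min(P/Pref_eff, 1)`
(waiting with a growing tumor erodes both eligibility and dose efficacy —
the eligibility-erosion loop). Death occurs when `P <= Pdeath` or
`B >= Bdeath`; it is absorbing, stocks freeze, and HRQoL is reported as 0
for the rest of the horizon so all trajectories have identical length.

## Scenarios, strategies and calibration

The three patient scenarios differ **only** in the tumor growth rate `g`:
complete response (`g = 0.006`/day), relapse (`g = 0.012`/day, also the
shipped default), and no infusion (`g = 0.020`/day). No other parameter is
scenario-specific. The two improvement strategies touch exactly one
parameter each: reduced delay sets `D` from 60 to 40 days, and enhanced
support raises `Uavail` from 2 to 6 h/day; a `combined` preset applies
both. `D = 60`, `D = 40`, the 180-day horizon and the 2 to 6 h/day support
range are fixed design inputs; every other default is a calibration choice.

The calibration contract is qualitative: under status quo the three
presets must classify (via the burden thresholds) as complete response,
relapse, and not infused, and the full scenario-by-strategy matrix must
reproduce the expected ordering of the four HRQoL measures — smaller drop,
faster recovery and higher peak under either strategy; durability gained by
reduced delay but not by enhanced support in the relapse scenario; and, in
the no-infusion scenario, eligibility restored by reduced delay while
support alone improves HRQoL pointwise without changing the outcome. The
shipped defaults were tuned against exactly this matrix, which the test
suite re-checks. Two structural choices came out of that calibration and
are worth recording:

* The burden weight in the physical target exceeds one (`wB = 1.5`). With
  everything normalized to `[0, 1]`, a weight below one cannot drive
  physical well-being low enough, before infusion and in the untreated
  patient, to erode eligibility and eventually cause death; the clamp on
  the target keeps the formulation well defined.
* Treatment intensity is dose-dominated rather than expansion-dominated.
  When net CAR T-cell expansion is strongly positive, outcomes bifurcate:
  tiny parameter differences flip a patient between cure and failure, and
  no growth rate produces a stable "respond, then relapse" middle course.
  With contraction dominating, the total kill effort scales smoothly with
  the infusion-time state, and the relapse scenario exists as a robust
  intermediate regime.

## The four HRQoL measures

All four are computed on the sampled grid, without interpolation, against
the pre-infusion reference `Qref = Q(D-)` (stored in the infusion record at
decision time, before the event):

* **drop** — `Qref - min Q` over `t >= D`, floored at 0; the minimum is
  taken at its first occurrence `tmin`.
* **recovery time** — first `t >= tmin` with `Q >= Qref`, in days since
  infusion; absent if never restored. With the default step the
  discretization error is at most `dt = 0.125` day.
* **peak** — maximum of `Q` on `t >= tmin`; restricting to after the
  minimum excludes the pre-dip shoulder.
* **durability** — a dichotomous measure of "steady, high-level
  equilibrium": the patient is alive at the horizon, terminal HRQoL
  retains at least `eps_peak = 0.90` of the peak, the mean slope over the
  final `Wdur = 30` days is at least `-eps_slope = -1e-3` per day, and —
  unless the trajectory never dipped below `Qref` — a recovery was
  actually observed. The last conjunct prevents a trajectory that
  plateaus below its pre-infusion level from counting as durable.
  The tolerance `eps_slope` separates the gentle residual drift of a
  controlled tumor from the accelerating decline of a relapse; both
  thresholds are calibration choices, as no closed-form definition of
  durability exists.

Response classification scans the post-infusion burden: complete response
if the minimum reaches `Bcr = 0.04` and the terminal burden stays at or
below `Brel = 0.25`; relapse if the minimum reaches `Brel` and burden
subsequently rises above it; otherwise no response. A declined infusion
(`not_infused`) and death before horizon (`died`) take precedence, in that
order. A "partial response" category is named in the clinical workflow but
is not produced by any preset and is not implemented as one.

## Numerical choices

* **Integrator**: fixed-step classical RK4 with auxiliaries recomputed at
  every internal stage. Fixed stepping keeps the infusion event exactly on
  a grid boundary (`dt` must divide `D` and `H`, validated up front),
  makes runs bit-reproducible, and avoids solver-dependent event location.
  The default `dt = 0.125` day was chosen so that halving the step changes
  every terminal stock by less than `1e-5` on the relapse default; the
  suite also verifies fourth-order convergence and a `<= 1e-6` match to
  the exponential closed form of the linear goal-seeking subsystem.
* **Safety clamp**: after each full step the stocks are clamped to
  `[0, 1]` (CAR-T to non-negative) and the pre-clamp excursion is
  recorded; an excursion above `1e-6` triggers a warning, as it would
  indicate a formulation or step-size problem rather than roundoff. The
  vector field is structurally bounded — every inflow vanishes at the
  upper bound or is target-limited, every outflow vanishes at zero — and a
  property sweep over random valid parameter sets requires excursions
  below `1e-9`.
* **Events and ties**: death is checked after each step and takes
  precedence over an infusion falling on the same boundary; the first grid
  index attaining a minimum or crossing a threshold is used throughout.
* **Degenerate inputs**: a tumor-free patient (`B0 = 0, g = 0`) stays
  tumor-free with analytically decaying CAR-T; zero adjustment rates
  freeze well-being; these and similar extremes are exercised by
  `run_extreme_conditions()`.

## Sensitivity analysis

`run_sensitivity()` perturbs each listed parameter one at a time by a
fraction `rel` (default 10%) below and above its value and reports the
percent change of HRQoL at the final simulation time against the
unperturbed run. It anchors on the relapse scenario — the richest
dynamics that still survive to the horizon; a dead-at-horizon baseline is
rejected with guidance, since a percent change against zero is undefined.
The default perturbation set covers all continuous rate, weight, threshold
and initial-condition parameters; `dt`, `D` and `H` are excluded because
perturbing them changes the integration grid or the measurement time
itself. A perturbation that violates a parameter invariant (for example
`Bdeath` pushed above 1) keeps its table row, flagged `skipped` with a
warning, so the strict plus-or-minus semantics are never silently clamped.

## What the generated data do and do not emulate

The scenario presets and the piecewise-linear fixture trajectories
(`make_fixture_trajectory()`) emulate the *shape* families of interest — a
flat course, a dip with recovery to a durable plateau, a dip without
recovery, and a relapse wave — with closed-form metric values for testing.
They are deterministic single-patient idealizations: there is no
measurement noise, no cohort heterogeneity, no patient covariates (age,
weight, sex, prior therapies), no hyper-progression after infusion, and no
re-treatment. Passing tests therefore demonstrate internal consistency of
the model and its measures, not predictive validity on real patients;
parameters were chosen for one illustrative disease setting and a
different indication would need recalibration.

## Problem sizes

The shipped configuration integrates 1920 steps per run (240 days at
`dt = 0.125`). The test suite runs the nine-cell scenario matrix at full
resolution, a 200-run random-parameter sweep at shorter horizons, a
100-fixture metric-oracle comparison, and coarse-step (`dt = 0.5`)
variants for the harness mechanics; these sizes keep the whole suite
around a minute on one core while leaving every scientific check at the
default resolution.

## Known limitations

Single-patient, deterministic, normalized scales: the model supports
what-if exploration of feedback structure, not clinical prediction. The
psychological submodel compresses adaptation, social activity and support
into one stock with a time-budget gate; side effects are one aggregate
severity; CAR T-cell kinetics are reduced to bolus, saturating expansion
and first-order contraction. The durability measure depends on two
tolerances with no external gold standard. Costs and resource use are out
of scope.
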