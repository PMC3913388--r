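---
title: "The glucosim model: equations, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The glucosim model: equations, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucosim)
```

glucosim is an educational simulator of glucose–insulin interaction in
insulin-dependent diabetes: a virtual patient with no endogenous insulin
secretion eats a fixed daily meal schedule and injects a fixed daily
insulin regimen, and the package computes the 24-hour periodic steady
state of blood glucose (BG), plasma insulin and the four glucose fluxes,
plus an HbA1c estimate. This vignette is the package's own account of the
model: every equation, parameter and numerical choice below is a design
decision of this package, documented so it can be criticised and edited
(all constants live in `model_constants()` and a YAML config read by
`load_config()`).

## Insulin absorption and the dose-indexed tables

Subcutaneous absorption of a dose $D$ (IU) is modelled by the sigmoid
cumulative fraction

$$F(t) = \frac{t^s}{T_{50}(D)^s + t^s}, \qquad T_{50}(D) = aD + b,$$

with $t$ in hours since injection. The half-absorption time $T_{50}$
grows linearly with dose — a larger depot absorbs more slowly — which
makes the kinetics genuinely nonlinear in dose and is the reason the
lookup tables are indexed by integer dose (0–40 IU) rather than scaled
per unit. The absorption rate $D\,F'(t)$ feeds a plasma compartment with
first-order elimination $k_e$, which drives a first-order effect
compartment ("active" insulin, the quantity the glucose fluxes see):

$$\dot X = D F'(t) - k_e X, \qquad \dot A = k_a (X - A).$$

Four absorption classes cover the classic preparations, with defaults
chosen to order the plasma peaks short < NPH ≤ Lente < UltraLente:

| class | $s$ | $a$ (h/IU) | $b$ (h) | $T_{50}$ at 10 IU |
|---|---|---|---|---|
| ACTRAPID_LIKE (short) | 2 | 0.05 | 1.7 | 2.2 h |
| NPH_LIKE (intermediate) | 2 | 0.09 | 4.5 | 5.4 h |
| LENTE_LIKE (intermediate) | 2 | 0.11 | 5.5 | 6.6 h |
| ULTRALENTE_LIKE (long) | 2 | 0.15 | 9.0 | 10.5 h |

$k_e = 5.4\,h^{-1}$ (plasma insulin half-life of about 8 min) and
$k_a = 1.2\,h^{-1}$, so active insulin tracks plasma insulin on a
\~50-minute scale — fast enough to respond within a meal interval, slow
enough to smooth injection spikes. With $s = 2$ the absorption tail is
heavy ($1 - F \sim (T_{50}/t)^2$), so responses are precomputed over a
360-hour internal horizon before being folded onto the day grid; a
48-hour horizon would strand more than 5 % of a large long-acting dose
outside the fold and visibly break daily mass balance.

The tables store the folded responses: row $d$ of each 41 × 97 table is
the periodic-day sum $\sum_k X(t + 24k\,\mathrm{h})$ sampled every 15
minutes. Under steady-state daily repetition of the regimen, shifting a
folded row circularly to the injection time and summing across
injections is *exact* superposition, including wrap-around of
long-acting tails past midnight. Tables are stored per unit distribution
volume; the engine divides by $V_i \cdot \mathrm{weight}$
($V_i = 0.142$ L/kg) only at simulation time, so one table set serves
every patient. Biphasic premixes (e.g. a 30/70 mixture) are split by
`biphasic_split()` into a short-acting and an intermediate-acting
injection at the same time and dose-rounded independently.

The nine ASCII storage files (`Actrapid_act`, `Actrapid_pa`, `NPH_act`,
`NPH_pa`, `Lente_act`, `Lente_pa`, `UltraLente_act`, `UltraLente_pa`,
`CAR`) hold one whitespace-separated 97-value row per dose or gram
offset under a header line; values are written with 15 significant
digits so the write/read round trip reproduces the tables to better than
$10^{-9}$.

## Carbohydrate absorption

Gastric emptying of a meal of $Ch$ mmol glucose equivalent (1 g
carbohydrate ≡ 5.551 mmol, from the 180.16 g/mol molar mass of glucose)
follows a trapezoidal rate profile: a 30-min linear ramp to
$V_{max} = 120$ mmol/h, a plateau of duration $Ch/V_{max} - 0.5$ h, and
a 30-min ramp down. Meals below the critical load
$V_{max}(T_{asc}+T_{des})/2 = 60$ mmol (≈ 10.8 g) keep the one-hour
width with a proportionally lower peak (a triangle). The emptied glucose
passes through a first-order gut compartment
($k_{gut} = 1.8\,h^{-1}$) whose outflow is the systemic glucose
appearance rate; total appearance equals the meal's glucose equivalent
to well within 1 %. The grams-indexed table (0–80 g, 81 × 97) is folded
and shifted exactly like the insulin tables.

## The glucose balance

Blood glucose in a well-mixed space $V_g \cdot \mathrm{weight}$
($V_g = 0.22$ L/kg) obeys

$$\dot G = \frac{\mathrm{gut}(t) + \mathrm{NHGB}(G, I_a) -
  \mathrm{periph}(G, I_a) - \mathrm{renal}(G)}{V_g \cdot \mathrm{weight}}$$

with the four fluxes in mmol/h for a nominal adult:

* **Renal excretion** — zero at or below the renal threshold of glucose
  (RTG); above it, $\mathrm{GFR} \cdot (G - \mathrm{RTG})$ with the GFR
  estimated from creatinine clearance (100 mL/min ≡ 6 L/h). Continuous
  at the threshold.
* **Peripheral utilization** —
  $\frac{G}{K_m + G}\,(u_0 + u_1 S_p I_a)$ with $K_m = 10$ mmol/L,
  insulin-independent uptake $u_0 = 45$ mmol/h (dominated by brain
  consumption, ≈ 33 mmol/h, at saturating glucose) and insulin slope
  $u_1 = 4.8$ mmol/h per effective mU/L.
* **Net hepatic glucose balance (NHGB)** — a signed lookup grid over
  (effective hepatic insulin $S_h I_a$, $G$), bilinearly interpolated,
  spanning +50 mmol/h (fasting production at zero insulin) down to −27
  mmol/h (uptake at high insulin and glucose). The grid is monotone
  non-increasing along both axes — a validity condition checked whenever
  constants are constructed — and arguments outside the hull are clamped,
  never extrapolated.
* **Gut appearance** — the table-derived series above.

The categorical physiology presets map "low/reduced, normal,
high/increased" to RTG 7/9/11 mmol/L, creatinine clearance 40/100 mL/min
(no increased preset exists), and hepatic/peripheral sensitivities
0.2/0.5/0.8.

The scale of these fluxes was set from back-of-envelope physiology
before any end-to-end run: a 150–200 g/day diet supplies 35–45 mmol/h on
average, basal hepatic output is 40–50 mmol/h, and a 20–50 IU/day
regimen in $V_i \cdot 70$ kg ≈ 10 L yields mean plasma insulin of
10–60 mU/L. With the defaults, an under-insulinised virtual patient
settles near 11 mmol/L (HbA1c ≈ 8.6 %) and a well-treated one near
5 mmol/L, which is the educational dynamic range the simulator needs.

## Integration and the periodic steady state

The day is integrated with an explicit Euler method on the 15-minute
grid (96 steps). Two numerical choices matter:

* **Driver sampling.** The meal and insulin driver series vary sharply
  within a step; sampling them at the interval *start* leaves a
  first-order error of ≈ 0.5 mmol/L against a 1-minute reference.
  glucosim therefore feeds each step the trapezoidal interval *average*
  of the two driver series, while the $G$-dependent fluxes remain
  explicit at the interval start. This halves the discretization error
  (to ≈ 1.7 % pointwise on the mid-range reference case) at no cost to
  the bookkeeping identity: every increment still equals
  $\Delta t \cdot \Sigma\,\mathrm{fluxes} / (V_g \cdot \mathrm{weight})$
  with the recorded drivers, to machine precision.
* **Steady state by day iteration.** Starting from $G \equiv 7$ mmol/L,
  the 24-h pass is repeated, each day starting from the previous day's
  final glucose, until the whole trajectory moves less than 0.01 mmol/L
  (max-norm) between consecutive days; 50 iterations is a hard cap and
  non-convergence is an error, never a silent result. Because every
  removal flux is non-decreasing in $G$ and NHGB is non-increasing, the
  day map is a contraction and 3–5 iterations typically suffice; the
  converged day closes on itself ($|G(0) - G(24\,h)| <$ tolerance) by
  construction.

Simulated glucose is floored at 0.5 mmol/L: the model has no
counter-regulatory rescue, and an unbounded free fall under insulin
excess would be physiologically meaningless. The floor is an
educational-model artefact, and any regimen that reaches it should be
read as "severe hypoglycaemia", not as a prediction. A consequence for
verification: on scenarios that dip near the floor, a *relative*
pointwise comparison between step sizes is dominated by a ~1 mmol/L
denominator, so step-refinement agreement is assessed on a mid-range
case (BG ≈ 7–17 mmol/L), where the 15-minute and 1-minute solutions
agree within 5 %.

Meal and injection times are snapped to the nearest 15-minute grid
point, and doses/grams to the nearest integer table row (the tables are
integer-indexed; no interpolation between rows), with a message whenever
snapping changes a value.

## HbA1c

Mean BG is the arithmetic mean of the 96 interval start points (for a
periodic series this equals the trapezoidal time average). The default
HbA1c regression is
$\mathrm{HbA1c} = (\overline{BG}_{mg/dL} + 86)/33.3$ %; an alternative
inverting the estimated-average-glucose relation
$\overline{BG}_{mg/dL} = 28.7\,\mathrm{HbA1c} - 46.7$ is selectable via
`model_constants(hba1c_model = "eag")`. Whether the historical engines
time-weighted their mean is not documented; for a uniform grid the two
choices coincide anyway.

## Scenarios, sessions and reproducibility

A case scenario is a line-oriented `key: value` ASCII file: weight (kg
or lb, converted at 0.45359237 kg/lb), up to six meals, up to two
insulin preparations with up to four injections each, and the four
categorical physiology fields (defaulting to normal). `parse_scenario()`
/ `write_scenario()` round-trip canonical text exactly, and
`validate_scenario()` returns violations as data in a deterministic
order. The packaged database of 40 virtual patients is a
*reconstruction*: three cases follow documented narrative details and
the rest are authored afresh in the same style; they are teaching
material, not clinical records.

`random_scenario(seed)` generates valid fixture patients — weight 45–100
kg, 3–6 meals totalling roughly 100–250 g, a basal/bolus (70 %) or
twice-daily premixed (30 %) regimen of roughly 20–50 IU/day, categories
drawn uniformly — without disturbing the caller's RNG stream. These
ranges were chosen once as a realistic teaching population; they
emulate regimen structure only, not day-to-day variability, absorption
noise, exercise, stress or illness, so passing property suites on them
demonstrates internal consistency of the model, not fidelity to any
individual patient.

A session retains at most two runs (current + previous) for overlay
comparison, numbers runs from 1, and stamps a 5-digit session id into
the six exported two-column data files per run, so concurrent sessions
never collide. Identical inputs reproduce identical bytes.

## Known limitations

* The model is for education: no endogenous insulin secretion, no
  exercise/stress/illness effects, all carbohydrates treated as equal,
  no insulin analogues (lispro/glargine class preparations are out of
  scope), no per-patient absorption variability.
* All rate constants are plausible stand-ins calibrated as described
  above, not fitted to clinical data; absolute BG curves should not be
  compared against any real patient.
* The 15-minute explicit Euler grid is part of the method's definition;
  its discretization error (≈ 2 % mid-range, larger near the glucose
  floor) is documented above rather than hidden by a finer default.

## Problem sizes used in the checks

The test-suite and the acceptance script run: mass-conservation
integrals at 1-min resolution over 600 h for 4 classes × 3 doses;
carbohydrate integrals for 3 meal sizes; steady-state convergence and
day-boundary closure for 20 seeded random scenarios; one 1-min-step
reference solution of the mid-range case for the step-refinement
comparison; and the four-run dose/diet adjustment sequence. These sizes
make every statement above directly computable in seconds.
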