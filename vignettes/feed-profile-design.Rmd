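---
title: "Designing and verifying syringe-pump feed profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and verifying syringe-pump feed profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pumpfeed)
```

`pumpfeed` models a gear-reduced, multi-channel syringe pump and the
bioprocesses it feeds. This vignette explains the models behind each
module, the parameters that matter and their defaults, the numerical
choices, and what the package's simulations can and cannot say about
real hardware and real cultures.

## Pump kinematics

A servo motor turns a linear actuator through `n` optional worm-gear
stages; the actuator pushes the pistons of up to three parallel
syringes. Three constants connect volume to rotation:

* `gdf = 24^n` — each gear stage is a worm gear on a 24-tooth wheel, so
  rotation is divided by 24 per stage (0–2 stages supported).
* `r_S` (deg mm⁻¹) — motor rotation per millimetre of actuator travel.
  The prototype value is 90 deg mm⁻¹; sustained counter-pressure above
  about 1.5 bar wears the drive to 150 deg mm⁻¹ irreversibly, so both
  values are first-class and `r_S` should be re-verified on hardware
  periodically. The published specification table uses 150.
* `l_V` (mm mL⁻¹) — piston travel per millilitre, a property of the
  syringe barrel: 1.8 (50 mL), 5 (20 mL), 8 (10 mL), 57 (1 mL).

Cumulative rotation for a dosed volume is then
`set_rotation(t) = V_F(t) · gdf · r_S · l_V`. The actuator stroke is
40 mm; dosing is limited to 35 mm to stay clear of the end stops, so the
volume per syringe is capped at `35 / l_V` mL.

Two further published numbers deserve comment. First, the specification
sheet's maximum dosable volume for the 1 mL syringe (0.6034 mL) implies
`l_V = 58` mm mL⁻¹ while its caption states 57; both syringe variants
exist in the catalogue (`standard_syringe("1 mL")` and `"1 mL (58)"`)
and neither is silently corrected. Second, the printed minimum-flow
column is about 5.9% of the maximum-flow column, not the nominal 5%:
the motor's response is not perfectly proportional at its extremes.
`motor_calibration()` therefore keeps **two independent anchors** — the
measured rotation rates at 100% and at 5% speed, back-computed from the
50 mL / no-gearbox reference cells — instead of deriving the minimum
from the maximum. The third calibration constant, the linear gain
8.5234 deg s⁻¹ per %-speed from a speed-sweep regression, is used by the
controller; it is deliberately not forced to agree with the envelope
anchors, because the two characterisations were measured differently
and disagree by a few per cent.

## Feed profiles and compilation

A profile is an ordered list of segments — constant flow, linear ramp,
or exponential (`V_F(t) = b·(e^{a t} − 1)` with `b` in mL, `a` in h⁻¹).
Every segment has a closed-form integral, and a profile's cumulative
volume at time `t` is the sum of completed segment integrals plus the
partial integral of the active segment. Compilation therefore involves
**no numeric quadrature**: schedules are exact at machine precision at
every grid point, and refining the grid never changes boundary values.
The default grid is 30 s for feeding profiles and should be set to
milliseconds for purification programs, matching the two control
cadences the hardware uses; both are arguments, not constants.

The exponential fed-batch design follows from the substrate mass
balance (next section) under two assumptions: dosed substrate is
consumed essentially immediately (`c_S ≪ c_S0`), and maintenance is
negligible. Then a culture growing at `µ_set` consumes substrate at
`µ_set/Y_XS · c_X0 V_R e^{µ_set t}` mg h⁻¹, which the feed matches with

\[
\dot V_{in}(t) = \frac{\mu_{set} V_R c_{X0}}{Y_{XS}\, c_{S0}}\,
  e^{\mu_{set} t}.
\]

The culture volume is treated as constant in this law: over a typical
run the dosed volume is of the same order as the sample volume
withdrawn. `simulate_fedbatch(track_volume = TRUE)` lifts that
simplification for sensitivity checks.

For pump-validation runs that dose a whole syringe over a fixed horizon,
`b_factor(total, a, T)` = `total·e^{−aT}` sizes the prefactor so the
dosed volume reaches `total` at `T`; in that convention the dosed
volume is measured from the initial set point `b`.

Multi-channel designs compose single-channel profiles on a shared
timeline with zero-flow padding: `gradient_pair()` produces two
complementary ramps whose summed flow is constant by construction
(exactly, not to tolerance), and `purification_program()` sequences
load (4 column volumes), wash (5 CV), gradient (10 CV) and rinse (2 CV)
phases at a constant column inflow. Where a port drives two syringes in
parallel, profiles carry the stream flow and the per-syringe flow is
halved at compile time through the configuration's `n_syringes`.

## The tracking controller

The hardware control loop is deliberately simple: at each tick the
executed rotation (from the motor's rotation sensor) is compared with
the scheduled rotation; the integer motor speed is incremented by 1%
when behind, decremented when ahead, held when equal, and clamped to
[5%, 100%]. `simulate_tracking()` reproduces exactly this — a bang-bang
increment controller with no proportional term — with a 1 s default
tick. Within a tick the rate is constant, so integration is exact.

Two behavioural notes, both consequences of the increment structure:

* The loop has integral action: a constant rate disturbance is absorbed
  with zero mean tracking error. But the error dynamics are neutrally
  stable — a large initial mismatch between required and actual speed
  excites a persistent oscillation whose amplitude reflects that
  mismatch. In the regime the pump is designed for (exponential feeds
  starting at the 5% minimum speed) the mismatch is small and the
  oscillation stays within a few one-step corrections
  (`gain · speed_step · dt_control` ≈ 8.5 deg at defaults).
* Setpoint flows below the 5%-speed flow cannot be met by a running
  motor. By default the simulator holds the minimum speed and flags
  `oversupply`, mirroring the recommendation to keep speeds above 5%.
  With `allow_stop = TRUE` the controller instead duty-cycles between
  off and 5% — decrements below the minimum switch the motor off,
  increments re-engage at the minimum — which is how low exponential
  feeds are tracked in practice. The closed-loop growth workflow uses
  this mode.

The disturbance model is multiplicative Gaussian rate noise (relative
SD 2% by default) plus an optional constant bias, seeded per run. It is
this package's choice for exercising the loop, not a claim about the
hardware's physical noise source; the simulated oscillation has the
qualitative character of the measured one (zero-crossings every few
ticks, seconds-scale corrections).

`tracking_stats()` reports delivered-versus-scheduled volume errors.
On simulated 5 h exponential runs with default noise the mean absolute
relative error is a few tenths of a per cent — comfortably inside the
2–4% oversupply band observed gravimetrically on hardware, as it omits
real-world contributions (mechanical slack, balance drift, fluid
effects).

## The fed culture

The vessel obeys

\[
\frac{d(V c_S)}{dt} = \dot V_{in} c_{S0} - c_X\, q_S\, V,
\qquad
\frac{d(V c_X)}{dt} = \mu\, c_X V,
\]

with Monod uptake `q_S = q_S,max · c_S/(K_S + c_S)` and `µ = Y_XS·q_S`.
The biomass closure is the standard one (the feed-law derivation never
needs it explicitly). Defaults describe glucose-limited *E. coli* in
minimal medium:

| parameter | default | unit | why |
|---|---|---|---|
| `Y_XS` | 0.35 | mg_CDW mg_S⁻¹ | measured wildtype yield used in the feed law |
| `q_S_max` | 1.8 | mg mg⁻¹ h⁻¹ | supports µ up to ~0.63 h⁻¹, the batch maximum on glucose minimal medium; must exceed the largest set-point demand (µ = 0.4 needs q_S ≈ 1.14) |
| `K_S` | 0.005 | mg mL⁻¹ | small enough that substrate is consumed "immediately" (residual c_S/c_S0 < 10⁻²) while keeping the ODE well-posed |
| `ngam` | 0 | mmol_ATP g⁻¹ h⁻¹ | maintenance is negligible at these rates; the literature value 8.39 can be enabled and is converted to a substrate drain via `substrate_per_atp` |

As `K_S → 0` and `q_S,max → ∞` the model recovers the
immediate-consumption limit `c_X(t) = c_X0 e^{µ_set t}` analytically;
the test suite checks this convergence, the closure of the substrate
mass balance to 10⁻⁸ relative, and that each of the four growth-rate
settings (µ_set 0.1–0.4 h⁻¹ with their matched `c_X0`, `c_S0` and
syringe types) is hit within 2% by a noiseless closed loop.

Numerics: adaptive `lsoda` with absolute tolerance 10⁻¹⁰ on the
amount-scale states and relative tolerance 10⁻⁸; output is interpolated
to the requested grid; a state more negative than the tolerance allows
aborts with advice to tighten tolerances rather than silently clipping.
When the culture is driven by a simulated controller trace, the
delivered-volume curve is resampled to 180 s bins before
differentiation: the loop's second-scale dithering is far below the
metabolism's response time, and keeping tens of thousands of
discontinuities in the right-hand side would only punish the step-size
controller. The cumulative volume is interpolated, never re-fitted, so
no dosed volume is lost.

## Growth, yield and burden estimation

`estimate_growth_rate()` is an ordinary least-squares fit of
`ln(proxy)` on time — any proxy proportional to biomass works.
`fit_yield()` regresses µ on q_S **through the origin**, because the
µ = Y_XS·q_S relation neglects maintenance; pooling many (q_S, µ)
pairs into one slope is more reliable than any single ratio. An
optional intercept mode reports the unconstrained line's intercept as
an implied maintenance uptake, as a sensitivity check.

Burden decomposition compares wildtype and plasmid-bearing yields:
`q_S,load/q_S,µ = (Y_WT − Y_loaded)/Y_loaded`, total demand
`1 +` that fraction, load share `load/(1 + load)`. With
`Y_WT = 0.35` and `Y_loaded = 0.263`, the load costs 33% extra and
takes ~25% of total uptake. The loaded yield 0.263 is *derived* —
back-computed as 0.35/1.33 from the reported 33% — not an independently
measured value; it is the package's reference pair for exact-recovery
tests. Uncertainty propagates from slope standard errors by the
first-order delta method, with a seeded Gaussian bootstrap as a
cross-check (no published uncertainty exists to compare against).

## Synthetic data

The generators emulate the relevant measurement modalities:

* `synth_od_series()` — exponential growth with multiplicative
  lognormal noise (log-scale SD 3% default), sampled every 1.5 h like a
  routine plate-reader series;
* `synth_gravimetric_trace()` — scheduled volume at water density
  0.997 mg µL⁻¹ plus additive balance noise and optional linear
  evaporation;
* `synth_mu_qs()` — µ = yield·q_S·(1 + ε) with relative Gaussian ε;
* `synth_bead_diameters()` — truncated-at-zero normal droplet sizes.

Noise structures are modelling choices (the measurement campaigns never
published theirs). Every generator takes a mandatory seed, draws from a
local RNG stream, and restores the caller's RNG state, so identical
calls are byte-identical and nothing leaks through global state.
Because the generators share no code with the estimators they exercise,
parameter recovery is a genuine round trip; the suite also checks
recovery is unbiased across 100 seeds.

What passing these tests does *not* show: real OD series have
instrument-specific saturation and background, real balances drift
non-linearly, real µ–q_S data carry day effects and correlated
triplicates. The simulations validate the estimators' statistical
behaviour under clean assumptions, not the instruments.

## Problem sizes and determinism

The shipped tests and the acceptance script use: 5–10 h feed horizons on
a 30 s schedule grid; 1 s controller ticks (18 000–36 000 per run); ODE
output every 0.1 h; 7–12-point regression datasets; 100-seed
replication for unbiasedness. These sizes keep every individual check
well under a minute while leaving the statistical assertions
well-powered. All stochastic paths are seed-deterministic; the
acceptance script derives all of its randomness from its `--seed`
argument.

## Known limitations

* No torque, friction, trumpet-curve or counter-pressure mechanics: the
  1.4 bar counter-pressure ceiling is documented but not modelled, and
  the wear of `r_S` from 90 to 150 deg mm⁻¹ is represented only as two
  alternative constants.
* The motor below 5% speed is treated as off; its real (non-linear,
  unreliable) response is not modelled.
* No overflow-metabolite kinetics (acetate/lactate) and no
  oxygen-transfer limitation in the culture model.
* The feed is open-loop by design — there is no feedback from measured
  biomass to the schedule, matching the hardware's operating mode.
* Buffer chemistry of gradients (imidazole–conductivity mapping) is out
  of scope; the purification program is verified on flows and volumes
  only.
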