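# pumpfeed

Feed-profile compilation and closed-loop simulation for programmable,
gear-reduced syringe pumps in bioprocess development.

Small-scale bioprocess work — setting defined growth rates in shaking
flasks, running chromatography gradients, dripping uniform droplets —
needs dosing hardware that translates a *desired process outcome* into a
*motor-rotation program*. `pumpfeed` implements that translation and its
verification entirely in software, for the class of DIY syringe pumps
built from a servo motor, optional worm-gear reduction stages, and a
linear actuator driving up to three syringes in parallel:

* **Pump kinematics.** A dosed volume maps to motor rotation through
  `set_rotation(t) = V_F(t) · gdf · r_S · l_V`, where `gdf = 24^n` is the
  gear-down factor of `n` worm-gear boxes, `r_S` (deg mm⁻¹) the rotation
  per millimetre of actuator travel, and `l_V` (mm mL⁻¹) the syringe's
  travel-per-volume factor. From two calibrated rotation rates (100% and
  5% motor speed) the package derives the full flow envelope of any
  syringe/gear combination — from ~0.7 µL min⁻¹ (1 mL syringe, two
  gearboxes) to ~210 mL min⁻¹ (50 mL syringe, direct drive).
* **Profile design and compilation.** Feed profiles are ordered piecewise
  segments (constant, linear ramp, exponential) integrated in closed form
  into cumulative-volume curves and rotation schedules. Built-in designs:
  the exponential fed-batch law
  `V̇_in(t) = µ_set · V_R · c_X0 / (Y_XS · c_S0) · e^{µ_set t}`
  that sets a specific growth rate under carbon limitation, complementary
  ramp pairs for linear gradients at constant column inflow, and a
  four-channel His-tag purification program (load 4 CV / wash 5 CV /
  gradient 10 CV / rinse 2 CV).
* **Controller simulation.** The pump's discrete tracking loop — compare
  executed with scheduled rotation every tick, nudge the integer motor
  speed by ±1%, clamp to [5%, 100%] — is simulated exactly, including
  multiplicative rate disturbances and duty-cycling for setpoints below
  the 5%-speed flow.
* **Culture simulation.** The fed culture follows the substrate mass
  balance `d(V·c_S)/dt = V̇_in·c_S0 − c_X·q_S·V` with Monod uptake
  `q_S = q_S,max · c_S/(K_S + c_S)` and growth `µ = Y_XS · q_S`, so a
  compiled and controller-tracked feed can be verified to set the
  intended growth rate.
* **Growth and burden analysis.** Log-linear growth-rate estimation,
  origin-constrained yield fitting (`µ = Y_XS · q_S`), and the
  decomposition of a plasmid-bearing strain's substrate demand into
  growth and heterologous-load components:
  `q_S,total = q_S,µ + q_S,load`,
  `q_S,load = q_S,µ · (Y_WT − Y_loaded)/Y_loaded`.
* **Synthetic data.** Seeded generators for OD series, gravimetric dosing
  traces, µ–q_S datasets and bead-diameter samples, so every estimator is
  testable against known ground truth.

## Worked example: set µ = 0.1 h⁻¹ in a 50 mL shaking-flask culture

```r
library(pumpfeed)

cfg  <- pump_config(standard_syringe("1 mL"), gear_train(2), r_S = 90)
spec <- fedbatch_spec(mu_set = 0.1, V_R = 50, c_X0 = 0.03,
                      Y_XS = 0.35, c_S0 = 36)
spec
#> <fedbatch_spec> mu_set 0.1 /h, V_R 50 mL, c_X0 0.03 mg/mL, Y_XS 0.35, c_S0 36 mg/mL (b = 0.11905 mL)

schedule <- compile_schedule(exponential_fedbatch_profile(spec, t_end = 10), cfg)
schedule
#> <rotation_schedule> 1201 rows over 36000 s; final volume 0.2046 mL, final setpoint 604442.5 deg
```

The prefactor `b = V_R·c_X0/(Y_XS·c_S0) = 0.11905 mL` and the 10 h
cumulative volume `b·(e¹ − 1) = 0.2046 mL` are exact closed forms; the
final setpoint is that volume times `gdf·r_S·l_V = 576·90·57` degrees.
This feed's flow is below the 5%-speed envelope of the configuration for
most of the run (`validate_schedule()` reports it), which is why the
controller duty-cycles between off and 5% speed. The full closed loop —
compiled schedule → noisy tracking controller → substrate mass balance →
noisy OD sampling every 1.5 h → log-linear fit:

```r
ex <- simulate_growth_experiment(spec, cfg, t_end = 10, seed = 42)
ex$fit
#> <growth_fit> mu_hat = 0.1040 +/- 0.0032 h^-1 (n = 7)
ex
#> <growth_experiment> mu_hat = 0.1040 h^-1 (discrepancy 3.97% from set)
```

The culture grew at 0.104 h⁻¹ against a setpoint of 0.1 h⁻¹ — a 4%
discrepancy, dominated by the OD measurement noise, not by dosing error.

Metabolic burden from the fitted yields of a wildtype and a
plasmid-bearing strain:

```r
burden_decomposition(0.35, 0.263)
#> <burden_result> Y_WT = 0.3500, Y_loaded = 0.2630
#>   load demand  : 33.1% of growth demand
#>   total uptake : 133.1% of wildtype at equal mu
#>   load share   : 24.9% of total uptake
```

i.e. carrying the plasmid costs an extra 33% of the growth-associated
substrate demand, so about a quarter of everything the loaded strain
takes up goes into plasmid maintenance.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "pumpfeed", package = "pumpfeed")`, with subcommands
`envelope`, `design`, `compile`, `simulate-pump`, `simulate-culture`,
`fit-growth`, `burden` and `synth`.

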