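# stickleg

A neuro-mechanical simulator of how an insect leg stops and starts
stepping.

Walking legs do not halt at random points of the step cycle: a stick
insect's leg always comes to rest on the ground, in the stance phase, and
restarts either with a swing or with a stance depending on where the femur
is standing.  `stickleg` models the middle leg as three antagonistic
muscle pairs — protractor/retractor (thorax–coxa angle α), levator/
depressor (coxa–trochanter angle β) and extensor/flexor (femur–tibia angle
γ) — each driven by a half-centre central pattern generator (CPG) through
inhibitory interneuron relays onto separate **fast** and **slow**
motoneuron pools, and asks what coordination logic turns a single central
"stop" or "start" bit into that orderly behaviour.

The package is aimed at motor-control and computational-neuroscience
researchers who want an executable, testable version of that logic.

## The model in brief

* **Fast fibres step, slow fibres stand.**  Muscle activation follows
  first-order kinetics, `dA/dt = k_act (1 − A)` during motoneuron action
  potentials and `dA/dt = −k_r A` otherwise, with per-muscle stance/swing
  rate constants for the fast fibres (protractor 2.01/0.81 ms⁻¹,
  retractor 5.01/0.71, levator 15.01/8.01, depressor 5.01/5.01, extensor
  5.01/5.01, flexor 8.01/8.01) and slow rates exactly 100× smaller.
* **Residual stiffness holds posture.**  Slow fibres act as springs with
  stationary residual constants (protractor 15.0, retractor 25.5, levator
  10.0, depressor 8.8, extensor 34.0, flexor 4.3 mN/mm²) that common
  inhibitory motoneurons abolish during stepping (fully in swing, down to
  a small fraction in stance) and restore at a stop.  A joint at rest sits
  at the static balance
  `k₁ᵉᶠᶠ (l₁ − l_min,1) = k₂ᵉᶠᶠ (l₂ − l_min,2)`, and commanding a
  stationary angle means solving this for the recruitment levels
  `kᵉᶠᶠ = (r/r_c) k` with the overpowering side de-recruited.
* **Commands act on gates, never on the CPGs.**  The stop programme arms
  only while α̇ and γ̇ are decreasing (never stopping into a protraction),
  silences the fast pools as their last swing burst completes, boosts the
  slow pools into tonic firing, latches permanent ground contact when β
  reaches the contact angle, and finally shuts the slow pools off at the
  commanded posture.  The start programme releases the pools at CPG
  depolarization triggers — swing-first below a critical angle α_crit,
  stance-first at or above it, with lift-off only after the first
  retraction and flexion are complete.  The CPG drive conductances are
  constant in every run; the trace logs them so the invariant is checkable.

## Worked example

```r
library(stickleg)

cfg <- leg_config()        # packaged defaults; stop at 3 s, start at 6.5 s
sim <- leg_simulate(cfg)   # 10 s of model time, ~0.2 s wall time
summary(sim)
```

```
leg simulation, 10000 ms (free-running CPG period 807.7 ms)
  stepping excursions: alpha [62.0, 119.4], beta [24.3, 80.2], gamma [68.5, 110.5] deg
  final posture: alpha 88.567, beta 62.879, gamma 79.513 deg (max |vel| 1.62e-01)
```

The run steps for 3 s (period ≈ 800 ms), stops, rests, and resumes
stepping after the start command at 6.5 s — the "final posture" above is
mid-step because the trace ends while walking.  The event log shows the
coordination sequence:

```r
subset(sim$events, !startsWith(event, "beta"))
```

```
   time                event        value
 3000.0     slow_PR_enhanced   0.00000000
 3000.0     slow_EF_enhanced   0.00000000
 3000.0         stop_command 102.59259259
 3240.3       fast_EF_switch  -0.00728476
 3341.6       fast_PR_switch  -0.00255849
 3952.9 ground_contact_latch  34.00000000
 3952.9          slow_EF_off  89.27247621
 4023.8          slow_PR_off 100.59295658
 6500.0        start_command   0.00000000
 6500.0  start_mode_selected   0.00000000
 7282.2           PR_enabled   0.00000000
 7282.2           EF_enabled   0.00000000
 7282.2           LD_enabled   0.00000000
```

Reading it: at the stop command (α target 102.59°) the slow pools are
boosted; the fast extensor–flexor and protractor–retractor switches arm
during the decreasing phases of γ and α (the logged values are the angular
velocities at the switch); the leg finishes its swing, touches down and
latches ground contact at β = 34°; the slow pools shut off as α and γ
reach their stationary values; the start command selects swing-first mode
(value 0, because 102.59° < α_crit = 104°) and all pools are released at
the next levator depolarization, at 7282 ms.

Commanding a different standing posture:

```r
pro <- muscle_params("protractor", "slow")
ret <- muscle_params("retractor", "slow")
recruitment_for_target_angle(96, pro, ret)
#> protractor  retractor
#>  1.0000000  0.8363971
```

To hold the femur at 96° the retractor is de-recruited to 84% of its
reference level; simulating a stop with `alpha_s = 96` brings the leg to
rest at 96.000°.

Experiment helpers reproduce the standard protocols:
`stop_sweep()` (20 stop phases over one cycle), `posture_experiment()`
(three commanded postures and their restart modes),
`slow_boost_experiment()` (paired ablation of the slow-pool boost).
A command-line front end with subcommands `simulate`, `stop-experiment`,
`start-experiment`, `export-defaults` and `fixtures` is installed at
`inst/cli/stickleg.R`.

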