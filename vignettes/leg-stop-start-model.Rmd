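---
title: "A neuro-mechanical model of stopping and starting of stepping in an insect leg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A neuro-mechanical model of stopping and starting of stepping in an insect leg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
library(stickleg)
```

## The system being modelled

A stick-insect middle leg moves through three antagonistic muscle pairs:
protractor and retractor coxae at the thorax--coxa joint (angle $\alpha$,
increasing during retraction), levator and depressor trochanteris at the
coxa--trochanter joint (angle $\beta$, increasing during levation), and
flexor and extensor tibiae at the femur--tibia joint (angle $\gamma$,
increasing during flexion).  Each pair is driven by its own central
pattern generator (CPG) -- a half-centre pair of mutually inhibitory
neurons -- through inhibitory interneuron relays onto separate *fast* and
*slow* motoneuron (MN) pools.  Fast muscle fibres move the leg during
stepping; slow fibres maintain posture.  Stepping swing is levation +
protraction + extension; stance is depression + retraction + flexion.

Three properties organise everything the package does:

1. **Slow fibres carry a residual stiffness.**  Even without MN activity a
   slow muscle acts as a spring with stationary spring constant
   $k_\mathrm{res}$.  Common inhibitory motoneurons (lumped here into one
   logical unit, "CI") abolish this stiffness during locomotion -- fully in
   the swing phase, down to a small fraction in stance -- and release it
   again when the leg stops, so posture is held with virtually no neural
   drive.

2. **Recruitment sets the stationary angle.**  At rest the joint settles
   where the two residual spring tensions balance,
   $k^\mathrm{eff}_1 (l_1 - l_{\min,1}) = k^\mathrm{eff}_2 (l_2 - l_{\min,2})$,
   with $k^\mathrm{eff} = (r/r_c)\,k$ the spring constant corrected for the
   recruitment level $r$.  Commanding a stationary angle means de-recruiting
   whichever muscle would overpower at that angle; the other stays at the
   reference level $r_c$.  `recruitment_for_target_angle()` solves this in
   closed form.

3. **Stop and start commands never touch the CPGs.**  Central stop/start
   signals act exclusively on MN-level gates via the interneuron relays,
   conditioned on angle and angular-velocity sensory signals.  The drive
   conductances of all six CPG neurons are constant time series in every
   run -- an invariant the trace records and the tests assert exactly.

## Model components

### CPG half-centres

The membrane equations are two-variable relaxation oscillators: a
persistent inward current with instantaneous activation and slow
inactivation $h$, a leak current, a constant excitatory drive conductance,
and graded mutual synaptic inhibition within the pair.  This is the
minimal dynamics that yields the properties the coordination logic
consumes: a robust anti-phase rhythm, a plateau/silent distinction that a
single threshold ($V_{thr} = -50$ mV, an implementer-chosen value) can
classify, and a depolarization onset that start triggers can detect.  With
the default constants the free-running levator--depressor pair has a period
of about 800 ms, stable to well under 1% across cycles.

Phase classification uses the stance-active neuron of each system (C1
retractor, C4 depressor, C6 flexor): hyperpolarized below $V_{thr}$ means
the system is in its swing-like phase.  The tie at $V_{thr}$ is classified
stance-like, so a borderline potential never spuriously abolishes the
stance-phase residual stiffness.

### Inter-joint coupling through the levation angle

The levation angle $\beta$ carries the position/load signal that couples
the three systems.  When $\beta$ crosses a critical value -- 45° for the
protractor--retractor (PR) system, 55° for the extensor--flexor (EF) system,
with 0.5° hysteresis for debouncing -- a transient excitatory conductance
pulse (5e-3 µS for 20 ms) is delivered to the CPG neuron that should
become active.  Because the two critical angles differ, extension starts
later than protraction on the way up and finishes earlier on the way down.

The PR and EF oscillators are configured to run about 30% slower free than
the LD oscillator (`tau_scale`).  During stepping their phase transitions
are therefore always *pulse-timed*: the sensory crossing, not the
intrinsic escape, switches the half-centre, which locks protraction to the
lifted leg and retraction to the grounded leg.  This is a deliberate
entrainment regime, not a tuning accident: with equal intrinsic periods
the relative phases drift to wherever initial conditions put them.

### Motoneurons and muscles

MN pools are leaky integrate-and-fire units with a 2 ms refractory period.
Uninhibited, a fast pool fires tonically at ~420 Hz with inter-spike
interval variation near zero; relay inhibition gates it rhythmically.
Slow pools receive a twentyfold smaller common drive during stepping, and
a boost factor of 20 on that drive while they are "enhanced" after a stop
command -- this is the lumped implementation of the enhanced central
inhibition of their interneurons (disinhibition plus fuller recruitment of
the pool).

Each MN spike opens a 2 ms activation window.  Within a window the muscle
activation obeys $\dot A = k_\mathrm{act}(1-A)$ with the published
per-muscle, per-phase rate constants (fast fibres; slow rates are derived
as exactly one hundredth and never stored); outside it decays as
$\dot A = -k_r A$.  The update is the exact solution of the linear
equation over each step, which matters because the fast stance rates (up
to 15.01/ms) would destabilise any explicit scheme at practical steps.
The shared relaxation rate $k_r = 0.005$/ms (its printed value is not
recoverable; sharing between fibre classes *is* enforced) is chosen so
that a silenced fast muscle's force outlives its burst by ~200 ms: an
armed stop can then let the ongoing swing movement complete before the
leg settles.

Muscle force is a clamped linear spring,
$F = (r/r_c)(k_\mathrm{max} A + \tilde k_\mathrm{res}) \max(l - l_{\min}, 0)$.
Recruitment scales the whole spring constant, active and residual parts
alike; this is what makes the commanded angle an exact equilibrium of the
post-stop leg.  Length--angle maps are linear with equal and opposite
slopes within a pair (pair lengths sum to a constant); each muscle's slack
anchor is the angle at which it reaches its minimal length.  The flexor
anchor is placed so that the extensor/flexor residual balance sits at the
resting flexion angle of 90°; the protractor/retractor anchors put the
natural balance at $\alpha \approx 102.6°$, the default stationary
retraction angle.

Joints follow strongly damped second-order dynamics
$I\ddot\theta = \tau - b\dot\theta$.  The damping-dominated regime gives
smooth, monotone convergence to rest without overshoot; inertia values are
set so the damping rate stays within the stability region of the
fixed-step integrator.

## The stop programme

On a stop command, in order:

1. The common inhibitor is silenced immediately, restoring the full
   residual stiffness of all slow muscles.
2. The slow PR and EF pools are disinhibited into enhanced tonic firing.
   Recruitment levels for the commanded $\alpha_s$ (and the fixed
   $\gamma_s$) are computed at this moment.
3. The fast PR (resp. EF) gate *arms*, once per stop epoch, at the first
   instant $\dot\alpha < 0$ (resp. $\dot\gamma < 0$) -- the leg never stops
   into a protraction in the stance phase.  The pools actually fall silent
   when that swing-phase burst completes (the swing-to-stance transition of
   their CPG), so the last protraction and extension run to completion.
4. When both fast gates have closed and $\beta$ has come down to the
   ground-contact angle $\beta_{gc} = 34°$ (within 1.5°, not rising -- the
   depressor establishes the contact), both levator--depressor pools are
   inhibited and a permanent ground-contact latch holds $\beta$ exactly at
   $\beta_{gc}$.
5. The enhanced slow pools switch off, once, when their angle is within 2°
   of its stationary value with angular velocity below 0.05°/ms.  The
   recruited residual stiffness then holds the posture exactly.

Because the enhanced slow fibres add active stiffness proportional to the
residual constants on both sides of each joint, they speed convergence
toward the stationary angle without shifting it much; cutting them at the
stop command (config `rules$slow_stop_mode = "cut"`) slows the final
approach by a factor of ~1.2--1.8 in the paired ablation experiment.

The choice of $\beta_{gc}$ deserves a note: once the residual stiffness is
restored, the levator's residual spring opposes the depressor, and the
post-stop depression settles near 34° rather than at the deeper stance
angles reached during stepping.  $\beta_{gc}$ is therefore set at that
post-stop equilibrium -- the angle the grounded leg actually assumes -- and
the latch band (±1.5°) is crossed transversally on every descent.

## The start programme

The stationary retraction angle determines the restart mode, split at the
critical angle $\alpha_{crit} = 104°$ (the approximate midpoint of the
stepping excursion; the split angle is acknowledged as a somewhat
arbitrary modelling choice).  Ties go to stance-first.

* **Swing-first** ($\alpha_s < \alpha_{crit}$): all six pools are released
  when the levator CPG neuron C3 next reaches its depolarization trigger
  (90% of the free-running voltage range above rest).  The first movement
  is a levation; the rising $\beta$ then recruits protraction (45°
  crossing) and later extension (55° crossing).
* **Stance-first** ($\alpha_s \ge \alpha_{crit}$): the PR pools are
  released at the C1 (retractor) trigger crossing -- stepping resumes with
  a retraction while the leg keeps ground contact.  A standing-load pulse
  re-entrains the LD CPG into its depression phase at that moment.  The EF
  pools are released next, given PR active, when the flexor neuron C6 is
  at its trigger level.  Only when both the retraction and the flexion
  have completed (C1 and C6 back below $V_{thr}$) does the position signal
  initiate the levation phase, the LD pools are released, the latch is
  cleared and the leg lifts off.  The release order PR ≤ EF ≤ LD is
  structural.

The contact latch is cleared exactly when the LD pools are re-enabled --
at the release trigger for swing-first starts, at the end of the cascade
for stance-first starts -- which is what keeps the leg grounded through
the initial retraction.

## What the fixture generator emulates, and what it does not

`make_fixture()` builds the three standard experiment families: a
20-phase stop sweep within one cycle, the three-posture start-mode family
(targets 8° below, at, and 8° above $\alpha_{crit}$), and seeded
enhanced-vs-cut ablation pairs.  The seed jitters command times only; the
dynamics are fully deterministic.  These families emulate *protocols*
(when commands arrive, which posture is commanded), not biological
variability: there is no channel or synaptic noise, no trial-to-trial
muscle variability, no load perturbations and no substrate model.  A
passing sweep therefore demonstrates that the coordination rules are
correct and robust to command timing -- it says nothing about robustness
to noise or to perturbed mechanics, which real legs face.

## Numerical choices

* Fixed-step RK4 at `dt = 0.1` ms throughout, one loop for the coupled
  system; events are processed at step boundaries in a fixed order
  (sensors, commands, rules, neurons, muscles, mechanics), so event
  ordering is reproducible and runs are bit-wise repeatable.
* Muscle activation uses the exact exponential update (unconditionally
  stable); all other states use RK4.  Halving the step changes post-stop
  end-state angles by ~1e-5 degrees.
* Commands take logical effect at the first step at or after their
  scheduled time.  Threshold crossings use 0.5° hysteresis.
* Angles are clamped to anatomical ranges with velocity zeroing; in the
  default regime the clamps are never reached.
* Trace sampling every 1 ms (stride 10); the full state needed to replay
  the stiffness gating bit-exactly is logged.

Typical problem sizes: a 10 s run integrates ~100,000 steps over 30
continuous state variables and completes in well under a second; the full
acceptance analysis (20-phase sweep, three postures, ten ablation pairs,
step-halving check) runs in seconds.

## Known limitations

* Neuron and muscle constants stand in for a companion-level biophysical
  model; only the tabulated activation rates, residual spring constants
  and the 100x slow-rate rule are literature values, and
  `param_provenance()` marks everything else as companion-derived or
  implementer-chosen.
* Muscles are linear springs without force--velocity or series-elastic
  behaviour; there is no gravity, load, or substrate friction, so "ground
  contact" is a kinematic latch, not a contact force.
* The levator--depressor slow pools fire rhythmically like the fast ones
  (the tonic variant, available via `rules$levdep_slow_tonic`, destabilises
  ground contact -- a reproducible negative result of the model).
* Inter-leg coordination, walking-direction switching and the brain-level
  origin of the stop/start commands are out of scope.

## A worked run

```{r demo}
cfg <- leg_config()
sim <- leg_simulate(cfg)
summary(sim)
subset(sim$events, !startsWith(event, "beta"))[1:10, ]
```

```{r plot}
plot(sim, "angles")
```
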