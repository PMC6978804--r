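---
title: "Model and methods: neuromusculoskeletal simulation of rat gait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: neuromusculoskeletal simulation of rat gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`ratgait` simulates rat locomotion in the sagittal plane with a
neuromusculoskeletal model: an eleven-link rigid skeleton, 26 Hill-type
muscles, a two-layer spinal central pattern generator (CPG), and delayed
posture/speed regulators.  Gait is selected by a single ipsilateral
phase offset (walk pi/2, trot pi), and speed is modulated by the
extension-phase fraction beta of the gait cycle.  Energetics -- muscle
work, stride length, cost of transport (CoT) and its decomposition --
are computed from the simulated trajectories.

This vignette documents the model equations, the parameters and their
defaults, the numerical choices, the design decisions made where the
underlying description is open, and -- importantly -- the known
limitations of the reconstruction, including the trunk-support apparatus
under which all locomotion experiments run.

## Skeleton

The skeleton has eleven rigid links: a single trunk link (head
included), two-link forelimbs (brachium, antebrachium) and three-link
hindlimbs (thigh, shank, foot), giving 13 generalized coordinates: the
planar trunk pose (x, z, pitch) plus ten joint angles (shoulder and
elbow per forelimb; hip, knee and ankle per hindlimb).  Link masses,
lengths and moments of inertia are the measured values shipped in
`inst/extdata/default_params.yaml`; total mass is 0.1252 kg.  Joint
angles follow the anatomical convention: angles increase with extension,
and with all limb segments collinear and perpendicular to the trunk the
shoulder reads 120 deg, elbow 180, hip 120, knee 180, ankle 180.

Equations of motion are assembled for the kinematic tree from CoM
Jacobians (mass matrix) and velocity-product accelerations (bias
forces), which is algebraically identical to the Lagrangian formulation;
the test suite verifies the generalized accelerations against an
independent finite-difference Lagrangian oracle (relative residual
below 1e-5 on random states) and checks that passive contact-free motion
conserves energy to better than 1e-4 over one second at the working time
step.

Two elements are not fixed by the reference parameter set and are
our own modeling choices:

* **CoM positions within links** default to the link midpoint
  (configurable per link).
* **Joint-range stops.**  One-sided rotational spring-dampers act beyond
  10 deg and 180 deg at every limb joint (default stiffness 0.5 N m/rad).
  Without a hard stop at the straight joint the knee and elbow pass
  through 180 deg under load and snap through -- quiet standing is then
  impossible.  Since the reference gait ran with elbows and knees near
  full extension, load-bearing on the straight-limb stop appears to be an
  implicit part of that model, and we model the stop explicitly.

## Ground contact

Limb tips interact with the ground through viscoelastic elements:
vertical force `k_v * penetration + c_v * penetration_rate`, clamped
nonnegative; horizontal force from a spring-damper anchored at the
touchdown point.  The anchor slides when the horizontal force exceeds a
Coulomb friction cone `|F_x| <= mu * F_z` (default mu = 1.0): without
the cone the anchored foot of a swinging limb can be pinned to the
ground by arbitrarily large horizontal forces, which blocks swing
initiation.  Defaults are k_v = k_h = 1000 N/m and c_v = c_h = 5 N s/m,
giving about 1 mm of static penetration under body weight; none of
these constants belong to the reference parameter set, so all are
configurable.

## Muscles

Each muscle produces tension

    F_m = F_max ( a_m * fl(l) * fv(v) + fp(l) )

with activation `a_m` driven by first-order activation/deactivation
dynamics (time constants 11 and 18 ms).  Muscle kinematics use a linear
joint-angle map: at the neutral posture (shoulder 60, elbow 85, hip 70,
knee 90, ankle 100 deg) every uniarticular muscle sits at 85% and every
biarticular muscle at 75% of its maximum length; 2 deg of joint motion
corresponds to 1% of maximum length (BIC shoulder 4.5, GA ankle 1.5, GA
knee 4.5 deg).  Contraction velocity is normalized by 1.8 maximum
lengths per second.  Moment arms are constant (values in the
configuration file); a muscle with extensor action at a joint shortens
as that angle increases and contributes extensor-positive torque.

The three curve **shapes** are not part of the reference parameter set and
had to be chosen.  The defaults are:

* force-length `fl(l) = exp(-((l-1)/w)^2)` with **w = 0.3**.  The width
  matters structurally: the cycle-averaged shoulder torque of the
  nominal synergy weights is strongly retraction-dominant unless the
  narrow curve silences the strong biarticular retractor at its short
  stance length.  A width near 0.3 makes the early-stance shoulder
  torque approximately neutral, which is a property the working model
  must have had.
* force-velocity: concentric `(1 - v/v_max) / (1 + v/(v_max * c))` with
  **v_max = 3** (in units of the 1.8 l_max/s normalization) and
  c = 0.4; eccentric branch rising to a cap of 1.5.  v_max below about 3
  caps limb angular velocity so hard that the forelimb cannot complete
  its swing in the 0.1 s flexion phase at the model's stride lengths.
* passive `fp(l) = 0.02 (exp(6 (l-1)) - 1)` above maximum length, zero
  below.  No passive damping term is included: with link inertias of
  order 1e-6 kg m^2, even a parallel viscosity of 1% of F_max s/l_max
  suppresses the ballistic limb swings entirely.

The per-muscle maximum length `l_max` (only needed to express
contraction velocity in m/s for the energetics) is calibrated so the
linear length map is energy-consistent with the moment arm at each
spanned joint (`l_max = MA * coef * pi / 1.8`, averaged over joints for
biarticular muscles).  Absolute work and CoT magnitudes inherit this
calibration; CoT shapes and orderings do not.

## Motor control

**Rhythm generation.**  Four phase oscillators (one per limb) with
contralateral antiphase coupling (gain K1 = 20) and ipsilateral coupling
at offset Delta (gain K2 = 10): walking Delta = pi/2, trotting
Delta = pi.  The network's fixed point has the fore oscillator lagging
its ipsilateral hind oscillator by Delta; simulations start at the fixed
point by default (random initialization with a seed is available and is
used by the phase-locking tests).

**Pattern formation.**  Four rectangular pulses per limb (early/late
extension, early/late flexion) with onset/end phases
(0, 0.40, 1.24, 1.42) pi and (0.33, 0.89, 1.42, 1.71) pi at the nominal
extension fraction beta = 0.62, combined through the muscle-specific
synergy weights listed in the configuration file.  All four limbs share
the same schedule.

**Regulators.**  Shoulder height (BR, TRIL), hip height (VL, TA, SO) and
forward speed (SSP, SPD, IP, GM, TA, SO) are regulated by proportional
(-derivative) feedback on stance limbs only, with the tabulated gains, and
delivered with a 15 ms delay.  Stance is defined by actual tip contact
(vertical contact force positive) at sensing time; the command computed
from the sensed state is delayed, not the raw sensor.  Each limb's
height loop senses its own side's girdle height, computed analytically.

**Speed modulation.**  Changing beta rescales the pulse schedule (the
extension/flexion boundary stays at 2 pi beta), scales the
extension-pulse weights by (1-beta)/(1-beta_hat), and shifts the
regulator references linearly in beta.  Beta is ramped quasi-statically
at 0.005 per gait cycle (the ramp rate is a free choice; "slow" is taken
to mean quasi-static).  The sweep driver visits the grid
beta = 0.56 ... 0.68 outward from the nominal value, chaining each point
from the nearest steady gait.

## Integration and measurement

The coupled system -- 13 mechanical DoF, 26 muscle activations, three
per-muscle component activations for the CoT decomposition, 4 oscillator
phases -- is integrated with classical RK4 at dt = 0.02 ms.  Motor
commands are computed once per step (zero-order hold): oscillator phases
give the synergy command, the ring buffer supplies the regulator command
sensed 15 ms earlier, the sum is clamped to [0, 1].  Contact anchors and
events are updated at step boundaries.  A run aborts with a diagnostic
on numerical blow-up and is flagged as a fall when the trunk pitch
exceeds 60 deg or a girdle drops below 30% of its reference height.

Gait cycles are windows between successive right-hindlimb touchdowns
(debounced at 50 ms).  Mean speed is trunk-CoM displacement over an
integer number of steady cycles divided by elapsed time.  Positive and
negative muscle work are accumulated at full rate by trapezoidal
quadrature; negative (eccentric) work is divided by four in the cost of
transport `eps = W / D`.  The decomposition passes each command
component (synergy, posture, speed) through its own copy of the
activation dynamics and evaluates active-term tensions on the realized
muscle lengths/velocities; passive-term work is excluded from the
components and reported separately.  Because the activation dynamics
are nonlinear in the command, the components sum to the active-term
cost only approximately; the residual is reported.

## The trunk-support apparatus, and what this reconstruction does not do

The reference model walked freely.  This reconstruction does not: the
reference parameter set omits the muscle curve shapes, all contact constants, the
joint ranges and the initial conditions, and across a broad calibration
of those unknowns we did not find a configuration whose free gait is
stable.  The recurring failure is at the shoulder: with the tabulated
maximum tensions, moment arms and synergy weights, the cycle-averaged
shoulder muscle torque is retraction-biased at any posture from which
the short forelimb could support the trunk, and the front of the body
falls within one or two strides unless a small external stabilizing
force remains available.

All locomotion experiments therefore run under an explicit, quantified
**trunk-support apparatus** (analogous to the partial body-weight
support used in rodent treadmill studies): a height/pitch spring-damper
servo on the trunk (k_z = 500 N/m, k_pitch = 0.1 N m/rad), at full
strength for the first second, faded linearly over three seconds to a
sustained floor of 50% servo authority.  Steady-state measurements use
only cycles after the fade.  The support is part of the simulation
apparatus, not of the animal model: muscle work and CoT include no
contribution from it.  Under the default support the model walks and
trots stably across the whole beta sweep.

Consequences for the results, measured honestly rather than tuned away:

* The steady gaits are support-assisted and more "bounding" than the
  reference lateral-sequence walk: forelimb duty factors are below the
  commanded extension fraction.
* Nominal walking speed is about 0.3 m/s, roughly 1.5x the reference
  0.2 m/s, and swept walking speeds (about 0.28-0.41 m/s) sit above the
  reference 0.15-0.2 m/s band.  Trotting spans about 0.11-0.22 m/s and
  is slower than walking at most beta -- the reference ordering is the
  reverse.  The corresponding acceptance checks fail and are left
  failing.
* The CoT decomposition behaves as in the reference model: the synergy component
  dominates the posture and speed components in both gaits, and the
  minimum-CoT speed coincides with the maximum-stride-length speed.

Problem sizes used throughout (chosen to keep the full pipeline within
ordinary desktop budgets): nominal runs are about 8 s of simulated time
(assist window plus >= 10 measured cycles); sweeps visit five beta
values per gait with ramping at 0.005 per cycle, 5 discarded and 10
measured cycles per point.

## Other design decisions

* The nominal parameter list repeats the symbol for the last two pulse
  end phases; they are read as Psi_3 = 1.42 pi and Psi_4 = 1.71 pi,
  consistent with pulse 4 starting where pulse 3 ends.
* Oscillator phases are integrated inside the global RK4 step together
  with the mechanical state and activations (one coherent integrator).
* The summed motor command is clamped to [0, 1] after adding the
  regulator component, since the activation dynamics guarantee bounded
  activation only for commands in that range; each component command is
  clamped separately for its own activation copy in the decomposition.
* Initial conditions: simulations start at the gait's oscillator fixed
  point, the trunk at the beta-scaled reference heights, each limb posed
  consistently with its phase (stance limbs planted with a
  phase-appropriate fore-aft offset and joint rates that cancel the
  trunk's initial advance; swing limbs lifted), and the forward speed at
  the reference speed for the starting beta.
* Left and right limbs are identical (the parameter table gives one
  column per link type); no joint-limit values being stated, the stops
  above are the only range model.
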