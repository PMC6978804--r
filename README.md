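# ratgait

Forward-dynamic simulation of rat locomotion in the sagittal plane,
for researchers in computational neuromechanics who want a compact,
fully scriptable quadruped model to study gait generation and its
energetics.

The model couples:

* an **eleven-link planar skeleton** (trunk with head, two-link
  forelimbs, three-link hindlimbs; 13 generalized coordinates) with
  measured masses, lengths and inertias (total mass 0.1252 kg),
  viscoelastic ground contact at the limb tips, and Lagrangian
  equations of motion integrated by RK4 at dt = 0.02 ms;
* **26 Hill-type muscles** (6 per forelimb, 7 per hindlimb) with
  tension `F = F_max (a fl(l) fv(v) + fp(l))`, first-order
  activation/deactivation dynamics (11/18 ms), constant moment arms,
  and a linear joint-angle-to-length map (85%/75% of maximum length at
  the neutral posture, 2 deg per 1% length);
* a **two-layer spinal CPG**: four coupled phase oscillators
  (rhythm generation) drive four rectangular synergy pulses per limb
  (pattern formation) whose weighted sum is each muscle's feedforward
  command;
* **posture and speed regulators** (shoulder height, hip height,
  forward speed) acting on stance limbs with a 15 ms sensorimotor
  delay.

Gait is selected by one parameter, the ipsilateral phase offset Delta
(pi/2 walk, pi trot), and speed is modulated by the extension-phase
fraction beta (the swing duration stays fixed at 0.10 s, so the cycle
duration is `T = 0.10 / (1 - beta)`).  Per-cycle energetics report
positive/negative muscle work, stride length `D`, cost of transport
`eps = (eta+ + eta-/4) / D`, and the decomposition of the cost into
synergy, posture and speed contributions.

All locomotion experiments run under an explicit trunk-support
apparatus (a weak height/pitch servo, analogous to partial body-weight
support in rodent studies); the methods vignette
(`vignettes/methods.Rmd`) documents why free locomotion is not attained
by this reconstruction and exactly what the support does.

## Worked example

```r
library(ratgait)

## nominal walking: beta = 0.62, Delta = pi/2
cfg <- default_config()
tr  <- simulate_gait(sim_config("walk", duration = 8, cfg = cfg))
tr$status
#> [1] "ok"

## steady cycles after the 4 s support fade-in window
wd <- detect_cycles(tr)$windows
wd <- wd[wd$start >= 4, ][-(1:5), ]
en <- energetics_report(tr, wd)
round(c(speed = mean(en$speed), T = mean(en$duration),
        CoT = mean(en$eps), CoT_synergy = mean(en$eps_syn)), 3)
#>       speed           T         CoT CoT_synergy
#>       0.304       0.215       0.385       0.351
```

The mean forward speed (m/s), the measured cycle duration (s), the
cost of transport (J/m) and its dominant synergy component are
computed from the simulated trajectory.  A beta sweep for
either gait:

```r
sw <- sweep_beta("walk")     # ramps beta quasi-statically, 5 points
as.data.frame(sw)[, c("beta", "speed", "D", "eps", "eps_syn")]
```

A thin command-line driver is installed at
`inst/scripts/ratgait_sim.R` (`simulate`, `sweep` and `validate`
verbs).

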