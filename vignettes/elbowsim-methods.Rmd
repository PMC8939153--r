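---
title: "Model and methods behind elbowsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind elbowsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elbowsim)
```

## The model

`elbowsim` simulates a planar human elbow used as an interactive motor
task plant: a fixed upper arm and a rigid forearm joined by a
frictionless hinge, driven by one lumped flexor and one lumped extensor.
The joint obeys

$$I\,\dot\omega \;=\; T_{\mathrm{active}}(\theta, u, x_m)
  \;+\; T_{\mathrm{lig}}(\theta) \;-\; b\,\omega, \qquad
  \dot\theta = \omega,$$

with $\theta$ the flexion angle ($0$ = full extension), $I$ the
forearm-plus-hand inertia about the elbow, $b$ a viscous damping
coefficient, and $T_{\mathrm{lig}}$ a double-sided exponential ligament
torque

$$T_{\mathrm{lig}}(\theta) = k_\ell\left[
  e^{c_\ell(\theta_{\min}-\theta)} - e^{c_\ell(\theta-\theta_{\max})}
  \right]$$

that is negligible mid-range and rises steeply at the range-of-motion
(ROM) limits. The plane is treated as horizontal, so gravity does not
enter; the only passive torques are the ligament and the damping, whose
behavioral purpose is to make *stopping on a target* possible in an
otherwise frictionless world.

Active torque comes from one of three actuation modes sharing the same
straight-line geometry:

* **torque mode** — $T = (u_f - u_e)\,T_{\max}$;
* **force mode** — $T = u_f F_{\max}^{gen} r_f(\theta) -
  u_e F_{\max}^{gen} r_e(\theta)$;
* **muscle mode** — Hill-type two-element muscles transmit their tendon
  force through the same moment arms.

Each actuator runs in a straight line from an origin at distance $d_o$
up the humerus to an insertion at distance $d_i$ from the hinge; the
extensor inserts on the posterior (olecranon-like) extension of the
forearm, mirroring the elbow triangle. The law of cosines gives the
muscle–tendon length, and the moment arm is the tendon-excursion
derivative $r(\theta) = |\partial \ell_{mt} / \partial\theta| =
d_o d_i \sin\theta / \ell_{mt}(\theta)$, which the test suite verifies
against central differences to $10^{-6}$ relative.

### The muscle model

Each muscle is a contractile element (CE) in series with a nonlinear
elastic element (SEE); there is no parallel elastic element. The CE
force is $F_{\max}\, a\, f_L(\ell_{ce})\, f_V(v_{ce})$ with a Gaussian
force–length curve $f_L = \exp[-((\ell_{ce}/\ell_{opt}-1)/w)^2]$, a Hill
hyperbola on the concentric side and a slope-continuous exponential
eccentric branch saturating at `fv_ecc_max`. The SEE is force-free below
its slack length and exponential above it,
$F_{se} = F_{\max} c_1 (e^{c_2 \varepsilon} - 1)$ — compliant at low
force, stiffening with load. Activation follows first-order dynamics
with a fast rise (15 ms) and slow fall (50 ms) and a floor $a_{\min}$
that keeps the CE-velocity solve non-singular. Because both elements
carry the same force, the CE velocity is obtained by inverting $f_V$ in
closed form at the required force ratio, clamped into
$[0, f_{V,ecc}^{\max} - 10^{-6}]$; this clamping plus the $a_{\min}$ and
$f_L \ge 10^{-6}$ floors make the solve total. The whole coupled state
$(\theta, \omega, a_f, \ell_{ce,f}, a_e, \ell_{ce,e})$ advances with
classical fixed-step RK4 at $\Delta t = 1/150$ s, controls held constant
across each step (zero-order hold, as in a sampled interaction loop).

## Default parameters and how they were constructed

| parameter | default | unit | rationale |
|---|---|---|---|
| inertia $I$ | 0.075 | kg m$^2$ | forearm + hand about the elbow |
| damping $b$ | 0.3 | N m s/rad | makes the stop criterion attainable |
| ROM | 10–160 | deg | physiological elbow range |
| ligament $k_\ell$, $c_\ell$ | 10, 40 | N m, 1/rad | see below |
| $F_{\max}$ flexor / extensor | 1000 / 800 | N | plausible lumped strengths |
| $\ell_{opt}$, $w$ | 0.12, 0.45 | m, – | lumped elbow muscle |
| $v_{\max}$, $a_f$, ecc. ceiling | 10, 0.25, 1.5 | $\ell_{opt}$/s, –, – | canonical Hill values |
| SEE $c_1$, $c_2$ | 0.02, 30 | – | compliant toe, stiff at load |
| $\tau_{act}$, $\tau_{deact}$, $a_{\min}$ | 0.015, 0.05, 0.01 | s, s, – | standard activation dynamics |
| flexor $d_o$, $d_i$ | 0.2, 0.03 | m | ~3 cm moment arm; see below |
| $T_{\max}$, $F^{gen}_{\max}$ | 5, 250 | N m, N | torques comparable across modes |

Three groups of constants are not free numbers but *solved* at
construction time, and this is the package's central design decision:

1. **Tendon slack lengths.** Each muscle's slack length is solved so
   that, at the 90° start with activation at the floor, its CE rests at
   a prescribed fraction of optimal length with the tendon just taut.
   This guarantees `init_muscle_state()` has a well-bracketed isometric
   equilibrium everywhere the task operates.

2. **Rest-torque equilibria at start *and* target.** The activation
   floor leaves a few newtons of resting force in each muscle, so the
   product of resting force and moment arm creates a passive torque
   field that decides where the arm can be at rest. The extensor
   insertion distance is solved in closed form so the field vanishes at
   the 90° start (a trial started with zero excitation holds still to
   machine precision), and the extensor's resting CE stretch is solved
   by a one-dimensional root-find so the field vanishes again at the
   135° target. The target equilibrium is a *gentle saddle* (residual
   stiffness ~0.01 N m/rad): an arm braked to a turnaround near the
   target keeps $|\omega|$ below the 0.001 deg/s success threshold for
   tens of consecutive samples before drifting off. Without this
   construction the resting-force bias makes the strict velocity
   criterion unreachable for on–off control — the drift through the
   target window is orders of magnitude faster than the threshold.

3. **Geometry for integrator stability.** The Hill muscle with an
   exponential tendon is numerically stiff at low activation: the
   linearized CE-length dynamics at rest have eigenvalue
   $\lambda \approx -(c_2 \ell_{opt}/\ell_{slack})\,|v'(1)|\,
   (1 + c_1/a_{\min})$, and explicit RK4 is stable only for
   $|\lambda|\Delta t \lesssim 2.79$. At the fixed 1/150 s step, a short
   tendon ($d_o = 0.15$ m, $\ell_{slack} \approx 0.032$ m) gives
   $\lambda\Delta t \approx -4.5$ and the arm diverges *at rest*. The
   default origin distance 0.2 m lengthens the tendon to
   $\approx 0.08$ m, giving $\lambda\Delta t \approx -1.8$ while keeping
   the same ~3 cm moment arms. Ligament constants were likewise fixed
   from two a-priori constraints: penetration depth
   $\ln(E c_\ell / k_\ell)/c_\ell < 5°$ for a worst-case arrival energy
   $E \approx 5$ J, and oscillatory stability
   $c_\ell \sqrt{E/I}\,\Delta t \le 2\sqrt 2$.

## The goal-directed task and its controllers

The task: start at 90°, reach a target 45° away in flexion, success when
$|\theta - 135°| \le 2°$ *and* $|\omega| < 0.001$ deg/s, within a 5 s
limit; the trial auto-resets afterwards (full state, including muscle
substates — fresh equilibrium each trial). Success is evaluated once per
integration step on the post-step state, the finest granularity a
fixed-step loop can observe.

The 0.001 deg/s velocity gate is extremely strict — roughly the angular
speed of a clock's hour hand — and shapes both shipped controllers:

* `controller_bang_bang()` plays on/off taps at a fixed level (keyboard
  semantics: only timing and duration vary). Because excitations are
  sampled at 150 Hz, tap durations quantize to whole steps, so
  `tune_bang_bang_schedule()` fixes a tap pattern (a launch burst, one
  mid-flight brake tap) and bisects the *level* — a continuous constant
  that legitimately stays fixed within the trial — until the coasting
  turnaround lands close enough to the target saddle. The tuned trial
  then dips under the velocity gate for dozens of samples. The whole
  calibration is deterministic (~40 simulated trials).
* `controller_proportional()` emulates graded myoelectric drive: a
  proportional–derivative term on the angular error rides on a constant
  co-activation of both muscles. Co-activation is load-bearing, not
  decorative: it adds *lag-free* intrinsic stiffness and force–velocity
  damping around the target, which is what lets the loop settle through
  the velocity gate. Pure error feedback at gains strong enough to
  cancel the rest bias oscillates, because it acts through the 15/50 ms
  activation lag. Gains (kp = 0.02 /deg, kd = 0.002 s/deg, co = 0.3)
  were chosen by a design-time stability sweep.

Tuned schedules are written with pulse edges half a step off the sample
grid and recorded proportional streams with stamps half a step early, so
a CSV round-trip (15 significant digits) can never flip a sample on or
off; replayed files reproduce the original trials bit-for-bit.

## The synthetic EMG chain

The chain emulates a consumer sensor feeding a 10-bit microcontroller:
raw EMG is zero-mean Gaussian noise amplitude-modulated by the
activation trace (1 kHz, seeded), then full-wave rectified and low-pass
filtered at 2 Hz by an exact one-pole discretization of an RC
integrator (unit DC gain), quantized to 10 bits over 0–5 V, and
normalized per channel by rest/MVC calibration levels measured from
dedicated synthetic recordings; finally it is resampled to the 150 Hz
control rate by within-interval averaging. Co-activation survives the
mapping because both channels normalize independently. Amplifier gain
is set so the MVC envelope sits near 80 % of the ADC full scale
($\mathbb E|g\,a\,z| = g\,a\sqrt{2/\pi}$). On the two-burst
demonstration trace the full chain recovers the input with Pearson
r ≈ 0.99; recovery degrades gracefully for faster inputs because the
2 Hz envelope lags them.

What the generator does **not** emulate: motor-unit spike trains and
their non-Gaussian interference structure, electrode lift and motion
artifacts, mains interference, crosstalk between channels, and
fatigue-related spectral shifts. Passing the recovery test therefore
shows the processing chain is self-consistent, not that it would meet
the same r on a physical sensor.

## Numerical choices

* Isometric initialization brackets the CE length on $(0, \ell_{mt})$
  and bisects to a residual below $10^{-8} F_{\max}$ (typically
  $10^{-10}$); an absent bracket is reported as a configuration error.
* The force–velocity inverse is algebraic on both branches; the
  round-trip error on $[0, f_{V,ecc}^{\max})$ is at machine precision.
* Activations are clamped into $[a_{\min}, 1]$ after each full RK4 step;
  intermediate stages are evaluated leniently so stage excursions do not
  raise spurious validation errors.
* Ties between success and timeout at the same step resolve to success.
* Angles are degrees at every user surface (configs, CSV logs, task
  parameters) and radians internally.

Problem sizes used by the test suite and the acceptance script were
chosen to exercise each property at full resolution while keeping a
complete run in tens of seconds: 1000-angle geometry grids, $10^4$-point
inversion grids, 1 s integrator convergence studies against a 1/4800 s
reference, 5 s trial horizons (751 steps), four-trial sessions, and a
10 s EMG trace at 1 kHz.

## Known limitations

* The muscle constants are plausible lumped values, not fits to any
  individual; trajectories reproduce the qualitative flexion-task
  behavior (sub-second transport, braking, settling, co-activation
  advantages of proportional control), not any specific recording.
* The stiffness analysis above is linear; pockets of the state space
  (near-slack tendon at moderate activation during fast shortening)
  remain locally unstable for explicit RK4 at 1/150 s. The velocity
  clamps bound any excursion and the randomized-excitation containment
  tests pass, but a stiff or implicit solver would be the right tool if
  those regimes mattered scientifically.
* Success under bang-bang control leans on the constructed target
  equilibrium; with user-modified geometry or strengths the passive
  field moves and `tune_bang_bang_schedule()` may legitimately report
  that the task is not completable under on/off control.
* The CLI replaces live keyboard/mouse/EMG input with schedule files;
  there is no real-time guarantee anywhere.
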