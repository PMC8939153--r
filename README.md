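# elbowsim

A scriptable, headless simulation of a planar human elbow for motor
control research and teaching. The model is the classic interactive
musculoskeletal plant: a fixed upper arm and a rigid forearm on a
frictionless hinge, driven by lumped flexor and extensor actuators, with
the user's control signals — graded (EMG-like) or on/off
(keyboard-like) — closing the loop around a goal-directed flexion task.
Everything runs deterministically from configuration files and control
schedules, so experiments that would normally need a human at a
dashboard (motor adaptation protocols, actuation-mode comparisons,
myoelectric-control pipelines) become reproducible batch jobs.

## The model in brief

Joint dynamics (flexion angle θ, 0 = full extension):

    I ω̇ = T_active(θ, u, muscles) + T_lig(θ) − b ω,   θ̇ = ω

* **Actuation modes**: `torque` (controls map to joint torques),
  `force` (controls map to actuator forces times moment arms), and
  `muscle` — Hill-type two-element muscles: a contractile element with
  Gaussian force–length, Hill force–velocity (smooth eccentric branch),
  and first-order activation dynamics, in series with an exponential
  tendon that is compliant at low force and stiffens with load.
* **Geometry**: straight-line paths from the upper arm to insertions
  near the elbow; moment arms follow the tendon-excursion identity
  r(θ) = |∂l_mt/∂θ| = d_o d_i sin θ / l_mt(θ).
* **Passive components**: a double-sided exponential ligament torque
  confining θ to a physiological range of motion, and viscous damping
  that makes stopping on a spatial target possible.
* **Integration**: classical fixed-step RK4 at 1/150 s over the full
  coupled state, controls held constant across each step.
* **Task**: move from 90° to a target 45° away in flexion; success when
  the angle is within ±2° of the target *and* the angular speed is below
  0.001°/s, within a 5 s limit; automatic reset between trials.
* **Synthetic EMG chain**: seeded amplitude-modulated noise → full-wave
  rectification → 2 Hz linear envelope → 10-bit ADC → rest/MVC
  normalization → 150 Hz excitation stream, with co-activation of both
  channels preserved.

The methods vignette (`vignettes/elbowsim-methods.Rmd`) explains how the
default constants are constructed (rest equilibria at the start and
target angles, tendon lengths chosen for integrator stability) and why
the strict stop criterion is attainable at all.

## Worked example

```r
library(elbowsim)

model <- default_run_config()          # muscle-mode arm, standard task
sched <- tune_bang_bang_schedule(model)  # calibrate a keyboard strategy
trial <- run_trial(controller_bang_bang(sched, attr(sched, "level")), model)
trial
#> <trial_record> success, 330 steps (2.193 s), movement time 2.193 s
#>   terminal: theta = 134.921 deg, omega = 9.71e-04 deg/s

emg <- run_trial(controller_proportional(model$task), model)
emg
#> <trial_record> success, 218 steps (1.447 s), movement time 1.447 s
#>   terminal: theta = 134.053 deg, omega = 4.42e-04 deg/s

session <- run_session(4, as_controller_factory(
  controller_proportional(model$task)), model, seed = 1)
summarize_session(session, model$task)
#>   trial outcome movement_time peak_velocity terminal_error
#> 1     1 success      1.446667      440.8181      0.9470551
#> 2     2 success      1.446667      440.8181      0.9470551
#> 3     3 success      1.446667      440.8181      0.9470551
#> 4     4 success      1.446667      440.8181      0.9470551
```

The bang-bang trial launches with on/off taps at a calibrated fixed
level and coasts to a turnaround on the target (movement time 2.19 s);
the proportional controller grades its drive and co-activates both
muscles near the target, stopping faster (1.45 s) with under 1° of
terminal error. Identical seeds reproduce sessions bit-for-bit. Every
trial logs the full state per step — angle, velocity, excitations,
activations, tendon forces, element lengths, moment arms, passive
torques — as a data frame (`trial$series`) or CSV.

## Command line

```sh
inst/cli/elbowsim make-fixtures --out demo --seed 1
inst/cli/elbowsim simulate --control demo/bang_bang_schedule.csv \
    --kind bang_bang --trials 4 --out session1
inst/cli/elbowsim summarize --dir session1
```

`make-fixtures` emits a demo configuration (YAML, degrees at the user
surface), a tuned bang-bang schedule, a recorded proportional schedule,
synthetic EMG envelope traces and a rest/MVC calibration. `simulate`
writes `trial_<k>.csv`, `summary.csv` and an echo of the resolved
configuration; exit codes are 0/1/2 for success/runtime error/usage
error.

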