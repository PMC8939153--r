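Package: elbowsim
Title: Interactive Musculoskeletal Simulation of a Planar Human Elbow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A scriptable, headless simulation of a planar human elbow driven
    by lumped flexor and extensor actuators. Provides Hill-type two-element
    muscle models (contractile element in series with a nonlinear tendon),
    straight-line actuator geometry with tendon-excursion moment arms,
    passive exponential ligament and viscous damping torques, a fixed-step
    fourth-order Runge-Kutta integrator, proportional (EMG-like) and
    bang-bang (keyboard-like) control streams, a synthetic surface-EMG
    signal chain (amplifier, rectifier, linear envelope, ADC, MVC
    normalization), and a goal-directed flexion task engine with trial and
    session management and full per-step state logging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
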