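Package: cstcontrol
Title: Optimal Feedback Control Simulation and Strategy Inference for the
    Critical Stability Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modelling of the Critical Stability Task (CST), a
    one-dimensional virtual balancing task in which lateral hand movements
    drive an unstable cursor. Provides the hand-muscle-cursor state-space
    plant, a finite-horizon linear-quadratic-Gaussian solver with
    signal-dependent motor noise and sensory delay, a seeded trial simulator
    under Position Control and Velocity Control objectives, per-trial
    behavioural metrics (hand-cursor cross-correlation and lag, RMS ratio,
    state-space summaries), psychometric fitting of success rates to recover
    the critical instability, and a simulation-trained, posterior-calibrated
    support-vector classifier that infers the control objective underlying
    any trial from its cursor kinematics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
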