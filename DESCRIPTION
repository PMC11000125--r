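Package: bcimanifold
Title: Closed-Loop BCI Simulation and Neural-Manifold Analysis of Adaptation Versus Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a closed-loop brain-computer interface (BCI) center-out
    cursor task driven by a cosine-tuned Poisson population through a
    steady-state Kalman filter decoder, imposes visuomotor rotation
    perturbations on the decoder gain, and models behavioural compensation by
    a re-aiming agent. Provides a virtual center-out reinforcement-learning
    environment with a proximal policy optimization (PPO) trainer implemented
    in base R, and a principal-component manifold analysis comparing
    population activity before and after rotations: per-target centroid
    geometry, adjacent-centroid angle distributions, centroid angular
    displacement regressions, normalized activity differences, and absolute
    cosine similarity of means and principal components. The contrast between
    within-manifold adaptation (re-aiming) and manifold-modifying learning
    (network retraining) is the package's central analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
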