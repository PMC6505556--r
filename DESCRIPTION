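Package: halteredyn
Title: Haltere Structural Dynamics and Spike-Timing Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the structural dynamics of a flapping fly haltere in a
    rotating body frame with a three-dimensional Euler-Bernoulli beam
    finite-element model, recovers deformation angles and base strains, and
    converts strain histories into predicted campaniform-sensilla spike times
    with a linear-nonlinear (spike-triggered average plus sigmoidal decision
    function) encoding model. Includes cross-section property calculators for
    annular and plus-shaped stalks, rotating-frame inertial load generation
    with explicit Euler/centrifugal/Coriolis decomposition, Newmark implicit
    time integration, synthetic neural-filter and strain generators, and a
    scenario orchestrator that reproduces the deformation-mode and
    spike-timing analyses for the standard haltere geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    pracma,
    jsonlite
Config/testthat/edition: 3
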