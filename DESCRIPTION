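Package: refk3
Title: Noninvasive k3 Estimation for Slowly Dissociating PET Ligands
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compartmental kinetic modelling for dynamic PET with slowly
    dissociating (moderately reversible) tracers such as [11C]Pittsburgh
    compound B. Provides closed-form plasma-input forward models (one-tissue
    and two-tissue, reversible and irreversible), a three-parameter
    reference-tissue working equation for noninvasive estimation of the
    binding rate constant k3 with a fixed reference efflux rate, weighted
    nonlinear least-squares fitting under positivity constraints, a
    frame-based PET noise model, and Monte Carlo drivers that characterise
    the coefficient of variation and bias of the k3 estimate under varying
    noise, delivery and reference-tissue kinetics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
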