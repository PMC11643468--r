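Package: microsteer
Title: Real-Time Magnetic Microswarm Steering Simulator for Vascular
    Bifurcation Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional simulator for steering a swarm of magnetic
    nanoparticle chains through a multi-bifurcation vascular network by a
    capped magnetic field gradient. Implements a semi-static (inertia-free)
    force balance between the magnetic pulling force on field-dependent
    particle chains and Stokes drag in a Hagen-Poiseuille channel network
    flow, integrated on a two-rate major/minor loop with point-in-polygon
    collision detection, trajectory reflection and wall friction. Includes
    scripted steering policies standing in for a human teleoperator, a
    percent-to-goal success metric, parametric sweep harnesses with
    mean/standard-deviation reporting, and digital-shadow validation
    utilities (time to travel a fixed distance under a uniform gradient,
    percentage-difference comparison, and frame binarization with
    centre-of-mass tracking).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
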