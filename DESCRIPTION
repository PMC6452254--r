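Package: embodysim
Title: Embodied Sensorimotor Emergence and Fetal Development Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale simulator of embodied behaviour emergence and early
    (fetal) sensorimotor development. Per-muscle controllers -- chaotic
    logistic maps or Bonhoeffer-van der Pol (FitzHugh-Nagumo) oscillators --
    are coupled only through simulated two-dimensional body-environment
    physics. The package provides an insect-like legged robot whose
    locomotion emerges from embodiment-coupled chaotic maps, a simplified
    human fetus model in a fluid-filled uterus or on a flat plane, a Hebbian
    spinal learning loop, and a scaled-down spiking cortical sheet (leaky
    integrate-and-fire neurons with spike-timing-dependent plasticity) that
    self-organizes somatotopic body maps. Analysis metrics include Lyapunov
    exponents of iterated maps, phase-locking values, detrended fluctuation
    analysis, jerk and contact event rates, and cortical response
    segregation and multimodal-integration indices. Experiment drivers
    orchestrate locomotion emergence, wall adaptation, intrauterine versus
    extrauterine body-map learning, multimodal integration, and closed-loop
    spinal development studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
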