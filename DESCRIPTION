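Package: somaxon
Title: Two-Compartment Soma-Axon Models of Auditory Coincidence Detector Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction, simulation and analysis of two-compartment
    (soma/dendrite and axon) conductance-based neuron models of medial
    superior olive (MSO) coincidence detectors, parameterized by forward
    and backward electrotonic coupling strength so that passive somatic
    dynamics are invariant across configurations.  Includes a reduced
    sodium current with dynamic inactivation, a low-threshold potassium
    (KLT) current with frozen or dynamic gating, synaptic conductance and
    injected-current stimulus generators including phase-locked afferent
    spike trains, measurement protocols (reference sodium conductance,
    coincidence-detection sensitivity, tonic/phasic classification, slope
    sensitivity, refractory period), and V2-h phase-plane tools
    (nullclines, knees, fixed points).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
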