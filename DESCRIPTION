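Package: eiwaves
Title: Inhibitory Control of Evoked Traveling Waves in 1-D Cortical Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how recurrent inhibition and spike-frequency
    adaptation shape stimulus-evoked traveling waves in one-dimensional
    cortical network models. Provides a spiking excitatory/inhibitory
    theta-neuron network with distance-dependent random connectivity, the
    corresponding Wilson-Cowan-like mean-field reduction and its space-clamped
    excitability analysis, a 1-D neural-field simulator with exponential or
    Gaussian coupling kernels, computation of traveling-pulse solutions as
    homoclinic orbits of the wave ODE with branch continuation (folds and
    pulse-to-front transitions), and closed-form existence plus Evans-function
    stability analysis of the step-function (Heaviside) model, including
    eigenvalue tracking and Hopf-curve tracing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    Matrix,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
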