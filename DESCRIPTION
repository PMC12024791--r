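Package: erkfreq
Title: Frequency-Domain Analysis of the Growth-Factor-Driven ERK Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the MAPK/ERK signalling cascade as a
    frequency-selective filter. Implements a 16-state nonlinear ordinary
    differential equation model of growth-factor (EGF/NGF) driven ERK
    activation with negative and positive feedback, solves its steady
    states across ligand dose, linearizes the dynamics into a state-space
    system, extracts the minimal rational transfer function from ligand to
    activated ERK, and computes Bode modulation/phase curves. Periodic
    ligand waveforms (rectangular and triangular pulse trains, sinusoids)
    are decomposed into Fourier series and propagated through the transfer
    function to predict periodic ERK activation responses and their summary
    metrics (equilibrium level, cycle peak, gain modulation). A stiff ODE
    integrator provides the nonlinear ground truth for validating the
    linearized pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
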