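Package: aptrpes
Title: Time-Resolved Photoelectron Spectra of Conical-Intersection
    Dynamics Probed by Attosecond Pulse Trains
Version: 0.1.0
Authors@R:
    person("Deep", "Waters", email = "dwaters@example.org", role = c("aut", "cre"))
Description: Simulates pump-probe photoelectron spectroscopy of a molecule
    passing through a conical intersection. A two-state, two-mode diabatic
    vibronic model is propagated on a grid with a split-operator scheme
    (real and imaginary time, complex absorbing boundary), probe fields are
    synthesized as single Gaussian XUV pulses or attosecond pulse trains
    (harmonic combs), and the photoelectron spectrogram over pump-probe
    delay and electron kinetic energy is computed by first-order
    time-dependent perturbation theory on the ionized surface. Analysis
    helpers extract diabatic/adiabatic populations, electronic coherence,
    photoelectron band positions, and the delay-domain quantum-beat
    modulation that signals the coherence created at the intersection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
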