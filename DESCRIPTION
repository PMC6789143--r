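Package: cardiodyn
Title: Linear and Nonlinear Dynamical Analysis of Cardiomyocyte
    Contraction Motion
Version: 0.1.0
Authors@R:
    person("cardiodyn", "developers", email = "cardiodyn@example.org",
           role = c("aut", "cre"))
Description: Quantifies the contractile behaviour of beating cardiomyocyte
    cultures (e.g. hiPSC-derived cardiomyocytes) from bright-field video.
    Block-matching optical flow converts an image sequence into a
    contraction-motion waveform (mean tissue motion speed per frame), from
    which linear beat metrics (beat rate, peak-to-peak interval,
    contraction and relaxation velocities) and nonlinear dynamical
    measures are computed: the capacity dimension of the waveform via the
    variogram (variation-estimator) method, and the correlation dimension
    of its delay-embedded phase-space trajectory via the
    Grassberger-Procaccia algorithm, with autocorrelation-based delay
    selection and false-nearest-neighbour embedding-dimension selection.
    Includes seeded generators for synthetic contraction waveforms
    (including arrhythmia-like aberrations), fractional Brownian motion,
    Lorenz trajectories and rendered beating videos with known
    ground-truth motion, plus a batch pipeline and command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
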