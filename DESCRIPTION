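Package: dynabuffer
Title: Reconfiguration Dynamics and Dynamical Buffering of Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for end-to-end distance dynamics of intrinsically
    disordered proteins probed by single-molecule FRET and molecular simulation.
    Computes FRET observables (orientational factor, donor survival, mean transfer
    efficiency) from dye or distance trajectories, fits SAW-nu polymer distance
    distributions and scaling exponents, infers discretized one-dimensional
    diffusion landscapes (free energies and position-dependent diffusivities) from
    distance time series by transition-count likelihood with Bicout-Szabo rate
    matrices, reweights conformational ensembles against experimental efficiencies
    (salt-bridge energy corrections and Bayesian/maximum-entropy reweighting), fits
    nanosecond fluorescence correlation curves, converts efficiency correlation
    times to chain reconfiguration times, and decomposes the compensation between
    distance variance and intrachain diffusivity ("dynamical buffering").
    Includes Brownian-dynamics and Rouse-chain generators that produce synthetic
    inputs with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
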