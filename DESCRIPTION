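Package: scxkit
Title: Simulation, Quantification and Inference for Single-Cell Gene
    Expression Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end workbench for stochastic gene expression in
    single cells. Defines mass-action reaction networks for constitutive
    and bursty two-state transcription with nuclear mRNA export, solves
    them deterministically (ODE), stochastically (Gillespie direct-method
    SSA) and distributionally (finite state projection of the chemical
    master equation with a certified truncation error), renders synthetic
    two-channel fluorescence microscopy snapshots with ground truth,
    quantifies images (multi-class Otsu segmentation, difference-of-
    Gaussians spot detection, compartment counting), and infers rate
    parameters from count data by maximum likelihood and
    Metropolis-Hastings sampling, including a step-change drug
    perturbation of the mRNA export rate.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Matrix,
    deSolve,
    Rcpp,
    EBImage,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
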