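Package: collapseKinetics
Title: Cluster Kinetics of Myosin Binding and Concerted Release from Thin
    Filaments by Kymograph Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying the stochastic attachment and concerted
    detachment of single fluorescently tagged myosin-S1 molecules from
    regulated thin filaments imaged as kymographs. Provides a ground-truthed
    simulator of cluster occupancy dynamics and a Gaussian point-spread
    renderer, rolling-ball background subtraction, per-frame multi-Gaussian
    peak fitting with BIC model selection, photometric calibration of
    fluorescence intensity to integer myosin counts, nearest-neighbour
    linking of active regions into tracks, estimation of cluster-size
    transition matrices with their model-predicted counterparts,
    collapse-probability curves and inversion to effective detachment rate
    constants, and a reversible-jump MCMC sampler for univariate normal
    mixtures with an unknown number of components as an independent route
    from pixel intensity to myosin count.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    minpack.lm,
    tiff,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    readxl,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
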