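Package: corralfcs
Title: Simulation and Spot-Variation FCS Analysis of Corral-Confined Membrane Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying hindered lateral diffusion of membrane
    receptors confined by the cortical actin meshwork. Provides a Monte
    Carlo simulator of Brownian motion with transient trapping and
    corral-hopping inside a Voronoi confinement mesh, readout of
    fluorescence intensity traces through Gaussian observation spots,
    direct and multiple-tau autocorrelation of intensity traces with
    bleaching correction, fitting of the two-dimensional diffusion FCS
    model, log-normal summaries of transit-time populations,
    STED observation-spot calibration and the spot-size-dependent
    diffusion law D(d) with free/trapped/hop classification,
    double-exponential FRAP recovery fitting, and watershed-based
    counting of fluorescent beads. All analysis stages are exercisable
    on seeded synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    deldir,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    knitr
Config/testthat/edition: 3
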