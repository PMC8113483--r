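Package: mfmt
Title: Mesoscopic Fluorescence Molecular Tomography Simulation and
    Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A simulator and reconstructor for raster-scanned mesoscopic
    fluorescence molecular tomography (MFMT) of scattering tissue at
    0.1-3 mm depths. Provides digital phantoms (fluorescent beads,
    capillary tubes, longitudinal tumor series), CPU Monte-Carlo photon
    transport with a Henyey-Greenstein phase function, a
    diffusion-approximation Green's function, Born-linear Jacobian
    assembly, L1-regularized (FISTA) image reconstruction with L-curve
    and mutual-information based selection of the regularization
    parameter, mutual-information thresholding of the reconstructed
    volume, and conversion of reconstructions to cell counts and tumor
    volumes via a linear histology calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
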