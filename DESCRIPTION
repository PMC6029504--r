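Package: DBTrecon
Title: Simulation and Limited-Angle Iterative Reconstruction for Digital
    Breast Tomosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Synthesizes heterogeneous digital breast phantoms with
    microcalcification and mass inserts, simulates narrow-arc digital breast
    tomosynthesis (DBT) acquisitions with Poisson quantum noise, and
    reconstructs them with filtered back projection (Ramp and Shepp-Logan
    kernels), SART, MLEM and the total-variation-minimizing ASD-POCS
    algorithm. Quantifies contrast preservation under projection thinning
    (normal 15-view versus half 7-view acquisitions) with FWHM line-profile
    analysis, contrast-to-noise ratio, SSIM/MSSIM, RMSE and the universal
    image quality index, and orchestrates parameter sweeps, convergence
    studies and normal-versus-half comparison experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
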