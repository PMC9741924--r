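Package: pdus
Title: Power-Doppler Ultrasound Simulation, Registration and Clutter Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational model of power-Doppler ultrasound for peripheral
    perfusion imaging. Simulates radio-frequency echo ensembles from moving
    tissue (clutter) and perfusing blood scatterers using a Gabor point-spread
    model, spatially registers frames by two-stage cross-correlation speckle
    tracking, applies eigen-based (SVD/PCA) clutter filtering, and quantifies
    blood-echo power recovery. Includes the coherence-based Cramer-Rao lower
    bounds on 2-D displacement-estimation variance used to validate the
    speckle-tracking estimator, and decorrelation experiments for out-of-plane
    transducer motion and sample-size scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
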