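Package: tracsim
Title: Transcutaneous Alcohol Diffusion Modelling and Input-Profile Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of ethanol transport from the blood supply
    through a four-layer skin epidermis and a sensor air gap, using a
    one-dimensional transient diffusion-convection model with an imposed
    blood-side concentration boundary. Includes three parametric input
    concentration profiles (piecewise linear, exponential linear, Hoerl),
    hybrid Monte Carlo + BOBYQA fitting of profile parameters against
    averaged wrist-sensor time series, a synthetic cohort generator for
    %BAC trajectories, and model-application studies: skin-thickness
    sensitivity, stratum corneum transients, and peak-delay analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minqa,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
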