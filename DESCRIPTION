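Package: cortiled
Title: Optical, Thermal and Neural-Data Modelling for Cortical Micro-LED
    Optogenetic Implants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Modelling and analysis toolkit for chronically implantable
    micro-LED arrays used for optogenetic stimulation of the cortical
    surface. Provides a Monte Carlo photon-transport simulator for layered
    device/tissue stacks with Henyey-Greenstein scattering and Fresnel
    interfaces, irradiance spot and activation-contour metrics, an
    axisymmetric finite-volume heat solver for pulsed micro-LED sources,
    current-to-irradiance and infrared-camera calibration, accelerated-ageing
    time conversion, spike-train analysis (peri-stimulus histograms,
    time-locked classification, dose-response thresholds, spatial Gaussian
    fits), go/no-go behavioural session scoring, and seeded synthetic-data
    generators that emulate the experimental protocols end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    minpack.lm,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
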