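Package: erins
Title: State-Space Modelling and PID Control of ER Stress and Insulin
    Signalling
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Declarative kinetic modelling of the integrated unfolded
    protein response (UPR) and hepatic insulin signalling network.
    Provides a three-shape rate-term grammar (input drive, modulated
    activation, modulated decay) compiled to a fast C++ right-hand side,
    a TR-BDF2 stiff integrator with state bounds, steady-state-derived
    external inputs for the ER-stress and insulin drives, discrete PID
    controllers closed around the plant, a scenario battery contrasting
    diet-induced obesity (DIO) against normal chow diet (NCD) controls,
    qualitative-pattern calibration, and a synthetic densitometry
    generator emulating replicate western-blot observations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo:
    RcppArmadillo,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
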