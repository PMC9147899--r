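Package: microspotr
Title: Quantitation of Serum Antibody Reactivity from Antigen Microspot Titration
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the two-dimensional titration analysis of antigen
    microspot (protein microarray) immunoassays. Spot-level fluorescence
    tables over a printed antigen density series and a serum dilution series
    are reduced to a log-signal grid and fitted with the product of two
    generalized logistic (Richards) functions by Gauss-Newton nonlinear least
    squares with profile-likelihood confidence intervals. The fitted
    inflection point ("lnKD") and asymmetry parameter summarize polyclonal
    antibody reactivity in unit-free chemical terms; thermodynamic
    activity-coefficient curves make samples and isotypes directly
    comparable. Includes an equilibrium binding-model simulator for spot
    data, readers and writers for a simple CSV schema and a GenePix-like
    tab-separated dialect, conventional mid-point and end-point titer
    calculators for comparison, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
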