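Package: alphamass
Title: Fitting and Identifiability Analysis of a Neural Population Model of the EEG Alpha Rhythm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fitting a 22-parameter mean-field (neural population)
    model of the electroencephalographic alpha rhythm to power spectra, and for
    diagnosing which parameters the data actually constrain.  Implements the
    analytic model spectrum of the linearized excitatory-inhibitory population
    equations, a gamma likelihood for Welch spectral estimates with the overall
    amplitude profiled out, particle swarm and Metropolis-Hastings samplers of
    the posterior over physiological parameters, and identifiability
    diagnostics: per-parameter Kullback-Leibler divergences, Fisher information
    eigen-analysis (sloppiness), eigenvector-axis angles and directional
    spectral derivatives.  A synthetic-data module generates gamma-sampled
    spectra and noise-driven simulated EEG from known ground-truth parameter
    sets so the whole pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
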