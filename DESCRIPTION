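Package: nltsa
Title: Nonlinear Time Series Analysis: Embedding, Dynamic Invariants,
    Recurrence Spectra and Information Theory
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for nonlinear analysis of sampled signals: delay
    (Takens) embedding with deterministic and stochastic parameter
    optimization (auto-mutual information, false nearest neighbors,
    Ragwitz criterion), dynamic invariants (Grassberger-Procaccia
    correlation dimension, Kantz and Rosenstein largest Lyapunov
    exponents, unstable-periodic-orbit detection, detrended fluctuation
    analysis), recurrence quantification including spatially-resolved
    (SREPS) and time-resolved (TRAS) recurrence period/amplitude
    spectra, binned and nearest-neighbor information-theoretic
    estimators (entropy, mutual information, active information
    storage), and surrogate-based nonparametric statistics
    (time-reversal nonlinearity test, Monte-Carlo and cluster-based
    permutation tests). Includes seeded generators for the canonical
    benchmark systems (Lorenz, logistic map, correlated Gaussians,
    compound oscillations) used to validate the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    signal,
    MASS,
    jsonlite,
    withr,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
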