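Package: dfconn
Title: Dynamic Functional Connectivity via Low-Rank Spectral Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dynamic functional connectivity (dFC) analysis of
    multivariate biological time series. Every common dFC matrix -- sliding
    window correlation and covariance, co-fluctuation, instantaneous phase
    alignment, phase locking and wavelet coherence -- is represented as a
    per-frame weighted dyadic sum of factor vectors and eigendecomposed
    through the small Gram (temporal covariance) matrix of those factors,
    so the N x N connectivity matrix itself is never materialised. All
    downstream measures (Schatten norms, metastability, spectral distances,
    Frobenius alignment, projector distances, von Neumann entropy,
    reconfiguration speed and the functional connectivity dynamics matrix)
    are computed directly in eigenspace. Includes a planted-covariance
    benchmark generator for validation and a configuration-driven pipeline
    runner with a thin command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
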