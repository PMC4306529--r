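Package: synaptrack
Title: Tracking Slow Synaptic Gain Changes with Dynamic Causal Modelling of
    Cross-Spectral Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed dynamic causal modelling of complex cross-spectral
    densities using a two-source canonical-microcircuit neural mass model.
    The package linearizes delay differential equations describing four
    coupled neuronal populations per source, predicts complex cross-spectra
    over channels from modulation transfer functions, and estimates slow
    trajectories of intrinsic and extrinsic synaptic coupling around a state
    transition (for example seizure onset) by variational-Laplace model
    inversion. Competing hypotheses about which couplings change over time
    are adjudicated by Bayesian model comparison with evidence pooled over
    sessions. A synthetic-data module generates windowed cross-spectral
    datasets from known parameter trajectories for face validation and
    parameter-recovery assessment.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
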