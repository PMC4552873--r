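Package: dmfentropy
Title: Dynamic Mean-Field Modeling and Entropy Analysis of Whole-Brain Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analytically characterizes spontaneous versus
    stimulus-driven cortical synaptic activity in a dynamic mean-field model
    of coupled excitatory-inhibitory populations on a structural connectome.
    Provides feedback inhibition control calibration, a linear noise
    approximation engine (stationary means, Lyapunov covariance,
    autocovariance, cross-spectra), stochastic Euler-Maruyama simulation,
    Balloon-Windkessel hemodynamic forward modeling, differential-entropy and
    Kullback-Leibler analyses of multivariate Gaussian activity, and an
    empirical rest-versus-task fMRI entropy pipeline with synthetic-data
    generators for connectomes and surrogate ROI time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
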