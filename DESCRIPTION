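Package: megscan
Title: Head-Position Estimation from Non-Stationary MEG Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates non-linear forward-model parameters (head position)
    from resting-state MEG recordings.  The recording is segmented into
    quasi-stationary states with a Gaussian-emission hidden Markov model,
    each segment covariance is inverted with a parametric empirical Bayes
    scheme built on smooth cortical patch priors and restricted maximum
    likelihood, and variational free energies are aggregated over a grid of
    rigid head displacements by fixed-effects family-wise Bayesian model
    comparison.  Includes an analytic spherical-conductor MEG forward model,
    a surrogate-cortex simulator of gated non-stationary source activity,
    and plain-text serialisation of every intermediate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, signal
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
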