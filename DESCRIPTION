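Package: audenc
Title: Auditory Encoding Models with Short-Term Plasticity and Contrast Gain Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fitting and comparing spectro-temporal encoding models of
    auditory cortical neurons: the linear-nonlinear (LN) model with a rank-3
    spectro-temporal receptive field, its extension with short-term synaptic
    plasticity (STP) at the model input, its extension with contrast-dependent
    gain control (GC) at the model output, and the combined GC+STP architecture.
    Includes a gammatone spectrogram frontend, a synthetic stimulus and
    model-neuron generator for end-to-end testing, staged bounded optimization
    of model parameters, noise-adjusted prediction correlations, a
    partial-correlation model-equivalence analysis with split-half noise
    ceilings, and a signal-power reliability metric for repeated spiking
    responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    signal,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
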