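Package: tagstrain
Title: Pixelwise Eulerian Principal Strain Mapping from Tagging MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating two-dimensional Eulerian principal strain
    maps from pairs of line-tagged (1-1 SPAMM) magnetic resonance images at
    native image resolution. Provides a Monte-Carlo tagging-MRI phantom
    simulator of short-axis left-ventricle and liver motion with analytic
    pixelwise ground-truth strain, a harmonic-phase (HARP) bandpass baseline
    with configurable filter widths, a conditional generative adversarial
    network (U-net generator, patch discriminator) trained with a
    strain-weighted pixelwise loss under four loss-weighting schemes, input
    conditioning (resampling, de-rectification of magnitude tag images), and
    an evaluation kit (pooled pixel correlations, absolute-error histograms
    per strain bin, patch sampling for artifact review).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
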