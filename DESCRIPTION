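Package: domfit
Title: Dominance and Distribution of Fitness Effects Inference from Site
    Frequency Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating selection and dominance parameters for
    deleterious coding mutations from folded site frequency spectra under
    the Poisson random field model. Computes expected frequency spectra
    under arbitrary dominance with a Wright-Fisher diffusion engine,
    fits gamma and discrete distributions of fitness effects conditional
    on an inferred demography, enumerates and model-averages per-bin
    dominance models with AIC weights, and forward-simulates genetic load
    and inbreeding load (haploid lethal equivalents) under a two-population
    out-of-Africa history.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'sfs-io.R'
    'density.R'
    'diffusion.R'
    'expected-sfs.R'
    'dfe.R'
    'inference.R'
    'demography-presets.R'
    'forward-sim.R'
    'load-metrics.R'
    'synthetic.R'
    'pipeline.R'
    'RcppExports.R'
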