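Package: headingcells
Title: Heading Tuning, Functional Classification and Population Decoding for Rotating-Chamber Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-photon calcium imaging of heading-tuned
    cortical populations recorded in rotating-chamber sessions. Converts raw
    somatic and neuropil fluorescence into dF/F and inferred spikes, builds
    60-bin heading tuning curves, tests heading selectivity with Rayleigh-vector
    and trial-reliability shuffle tests, quantifies coherent remapping and
    tuning-curve bimodality (flip score), classifies cells into heading,
    landmark and alignment functional classes with a Gaussian-mixture model on
    sum-of-Gaussians fit coefficients, and decodes heading from bootstrap
    pseudopopulations with a naive Bayes decoder. Includes a synthetic-session
    generator that emulates controlled-rotation experiments with light-on and
    light-off phases, so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    cluster,
    mclust,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
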