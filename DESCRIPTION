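Package: conntracer
Title: Validation of Tractography Connectomes Against Retrograde Tract
    Tracing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how well structural connectomes
    estimated from diffusion MRI tractography reproduce invasive
    retrograde tract-tracing measurements over a shared cortical
    parcellation. Implements fraction-of-labeled-neurons (FLN) and
    fractional-scaling (FS) normalization of raw count matrices,
    rank and log-Pearson association with percentile bootstrap
    confidence intervals, distance-regressed partial Spearman
    correlation, progressive strongest/weakest edge-removal robustness
    curves, and density-thresholded detection performance
    (sensitivity, specificity, precision). A synthetic generator of
    paired tracer/tractography experiments with lognormal weights,
    exponential distance decay, multinomial tracer sampling and
    distance-dependent streamline dropout makes the whole pipeline
    testable without imaging or histology data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'association.R'
    'conntracer-package.R'
    'detection.R'
    'io.R'
    'normalization.R'
    'synthetic.R'
    'robustness.R'
    'pipeline.R'
    'utils.R'
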