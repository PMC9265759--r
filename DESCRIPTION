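Package: awflow
Title: Accelerated Wirtinger Flow for Pixel Super-Resolution Lensless Phase Retrieval
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction of complex sample transmittance from stacks of
    low-resolution intensity images recorded by a lensless on-chip microscope
    with phase-modulation diversity. Implements the full optical forward model
    (phase-only modulation, angular-spectrum free-space propagation, sensor
    cropping and sub-pixel binning) together with its adjoints, an accelerated
    Wirtinger flow solver with Nesterov momentum and a proximal step for
    anisotropic complex total-variation regularization, a spectral-radius rule
    for automatic step-size selection, a synthetic-data generator emulating
    modulation-diversity acquisitions, and ambiguity-aware reconstruction
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'awflow-package.R'
    'evaluation.R'
    'io.R'
    'optics.R'
    'regularization.R'
    'solver.R'
    'synthetic.R'
    'utils.R'
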