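Package: arborMetrics
Title: Quantitative Morphometry of Bistratified Retinal Neuron Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative morphometric analysis of single-neuron
    reconstructions of narrow-field, bistratified retinal interneurons (AII
    amacrine cells). Reads SWC reconstructions with a layer/soma annotation
    sidecar, decomposes dendritic trees into branch segments under centrifugal
    and central-shaft ordering schemes, computes the full per-cell metric table
    (lengths, frusta surface areas and volumes, partition asymmetry,
    bifurcation angles and tilts, contraction, fractal dimension, helicity),
    detects dendritic varicosities from radius profiles, derives Sholl-sphere
    and laminar profiles, 2D/3D convex-hull dendritic-field metrics with exact
    Feret calipers, and the branch density versus territory volume scaling fit.
    Population-level analysis covers metric normalization with redundancy
    exclusion, correlation-matrix PCA with Monte-Carlo and broken-stick
    eigenvalue significance, bootstrap coefficient z-scores with sign
    correction, regression of excluded metrics, Ward clustering, and analytic
    random-branching angle baselines. A stochastic generator of bistratified
    arbors with complete ground truth supports validation, and a multi-photon
    excitation optics calculator checks Nyquist sampling of the acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
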