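Package: conceptManifolds
Title: Geometry of Concept Manifolds and Few-Shot Classification Error
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates the geometric properties of concept manifolds --
    point clouds of activity patterns (fMRI voxels, model units) evoked by
    exemplars of a visual concept -- that determine the error of few-shot
    prototype classifiers: geometric Signal, Bias, participation-ratio
    Dimensionality, Noise-Signal and Noise-Noise Overlaps, and the
    geometric signal-to-noise ratio SNR(m) that predicts m-shot error
    through a Gaussian tail function. Provides the empirical nested
    resampling protocol for m-shot prototype classification, random
    subspace selection and Gaussian random projection with convergence
    sweeps, a synthetic manifold generator with analytic ground-truth
    geometry and a trial-to-trial measurement-noise model, and
    second-order covariation analyses (log-linear Overlap model, iso-SNR
    surfaces in the Signal-Dimensionality plane, permutation-tested
    correlations, concept-hierarchy path distances).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, DimensionReduction, Classification
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'ActivitySet.R'
    'geometry.R'
    'fewshot.R'
    'projection.R'
    'synthetic.R'
    'covariation.R'
    'io.R'
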