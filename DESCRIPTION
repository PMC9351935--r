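Package: fmrikit
Title: Multisubject fMRI Analysis: Intersubject Correlation, Shared
    Response Modeling, Event Segmentation, Inverted Encoding and
    Realistic Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis methods for multisubject functional MRI time series
    after preprocessing, operating on time-by-voxel matrices. Implements
    intersubject correlation (ISC) and intersubject functional correlation
    (ISFC) with nonparametric permutation, circular-shift and
    phase-randomization tests; functional alignment via the shared response
    model (orthonormal per-subject transforms into a low-dimensional shared
    space, fit by alternating orthogonal Procrustes updates); left-to-right
    hidden Markov model event segmentation with constrained
    forward-backward inference; inverted encoding models over
    rectified-cosine channel bases for stimulus reconstruction; a generic
    volumetric searchlight engine; and a realistic fMRI noise simulator
    (drift, autoregressive, physiological, spatial and system components
    with an iterative fit to target SFNR and autocorrelation) that doubles
    as the package's synthetic-data engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
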