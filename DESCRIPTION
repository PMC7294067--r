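Package: cpmorph
Title: Injury-Robust Structural MRI Morphometry and Structure-Function
    Modelling for Unilateral Cerebral Palsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies brain structure from paired T1/T2 volumes in the
    presence of severe unilateral or bilateral injury, and relates the
    resulting measures to hand-function scores. Provides a synthetic brain
    phantom generator with analytic ground truth (tissue classes, lateral
    ventricles, deep gray matter, internal capsule, corpus callosum, cortical
    parcels, and parameterised injury: ventricular enlargement, periventricular
    T2-hyperintense lesions, cortical atrophy); preprocessing (bias-field
    removal, histogram matching, Perona-Malik anisotropic diffusion, affine
    atlas alignment, region-growing skull stripping); EM tissue segmentation
    with a T2-weighted lesion class and ventricle extraction; CSF-masked
    patch-SSD label propagation for deep structures; voxel-based cortical
    thickness, sulcal depth and curvature; and random-forest regression of
    motor scores with laterality-interaction terms under data-driven and PCA
    feature selection.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    ranger,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
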