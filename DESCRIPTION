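Package: lesionmorph
Title: Lesion-Aware Grey-Matter Morphometry for Cerebral Small-Vessel Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tissue segmentation and grey-matter morphometry for brains
    carrying small-vessel-disease lesions. Provides a synthetic
    brain-phantom and cohort generator with known ground truth;
    prior-weighted multivariate mixture-of-Gaussians tissue segmentation of
    T1/FLAIR image pairs; a lesion repair step that reassigns white-matter
    hyperintensity and lacunar-infarct probability mass to the correct
    tissue classes; stationary-velocity diffeomorphic registration with
    group-template construction and Jacobian modulation; voxel-based
    cortical thickness by Laplace-equation streamline integration;
    voxel-wise multiple regression with random-field-theory family-wise
    error correction and a max-statistic permutation alternative; and
    kernel Gaussian-process regression with confound correction for
    predicting lesion load from grey-matter maps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
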