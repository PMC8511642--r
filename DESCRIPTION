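Package: cardiot2
Title: Respiratory Motion-Registered Whole-Heart 3D T2 Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction pipeline for free-breathing
    isotropic whole-heart myocardial T2 mapping from ECG-triggered
    T2-prepared 3D radial (spiral phyllotaxis) acquisitions. Includes a
    Bloch simulator of the T2-prepared bSSFP sequence, a dynamic numerical
    thorax phantom with respiratory motion, superior-inferior self-navigation
    with PCA-based respiratory binning, a respiratory motion-resolved
    compressed-sensing reconstruction (finite differences along the
    respiratory dimension, nonlinear conjugate gradient), translational and
    non-rigid registration of respiratory bins and prepared volumes,
    voxel-wise two- and three-parameter T2 fitting, and map quality metrics
    (coefficient of variation, sigmoid edge sharpness).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
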