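Package: bhctvi
Title: Breath-Hold CT Ventilation Imaging by Deformable Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes deformable-image-registration (DIR) based breath-hold
    CT ventilation images from paired expiration/inspiration thoracic CT
    volumes. Provides multi-resolution B-spline free-form registration with
    the expiration phase as the fixed reference, Jacobian-determinant
    ventilation maps with percentile conversion and highly-functional
    classification, Hounsfield-threshold lung segmentation with left/right
    labelling and regional volumetry, cranio-caudal section reporting,
    displacement-vector-field orientation statistics relative to gravity for
    different body positions (supine, prone, lateral decubitus), and paired
    Wilcoxon signed-rank comparison of section ratios across positions. A
    synthetic thorax phantom with analytically known deformation fields
    supports validation of every stage without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
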