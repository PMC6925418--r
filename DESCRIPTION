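Package: voirad
Title: Sensitivity of MRI Radiomics to Volume-of-Interest Delineation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how differences in volume-of-interest (VOI)
    delineation propagate through an MRI radiomics analysis. A baseline
    tumour mask is perturbed slice-by-slice with morphological erosion,
    Gaussian smoothing and dilation of several radii; a 2068-feature
    radiomics vector (four geometric features plus grey-level co-occurrence,
    run-length, size-zone and neighbourhood grey-tone difference texture
    features over a grid of voxel sizes, quantization algorithms and grey
    levels) is extracted per delineation variant; feature robustness is
    scored with the intra-class correlation coefficient; features are
    selected by minimum-redundancy maximum-relevance ranking followed by
    0.632+ bootstrap AUC ranking; incremental random-forest models are
    compared across variants with the DeLong test, including a cross-variant
    transfer AUC matrix. A synthetic two-class 3D lesion cohort generator
    with controllable texture and intensity effect sizes makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    data.table,
    jsonlite,
    ranger,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
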