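Package: lesionmapr
Title: Spatial Mapping of Tumor Lesions in Whole-Body PET-CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An image-registration-based framework for studying spatial
    tumor heterogeneity in whole-body PET-CT cohorts. Selects sex-specific
    template spaces from negative controls by image body-fat percentage,
    estimates deformable subject-to-template transforms with cost-function
    masking around lesions, transfers segmented lesion masks and voxel-,
    lesion- and subject-level feature maps to template space per lesion,
    aggregates them into voxel-wise frequency, mean and
    coefficient-of-variation maps, and quantifies how the mapping perturbs
    lesion volumes and inter-lesion distances. Includes a synthetic
    whole-body CT/PET phantom cohort generator with known ground-truth
    warps for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
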