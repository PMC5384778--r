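Package: rtfuse
Title: Hybrid Image Registration and Dose Accumulation for Radiotherapy CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Registration of paired radiotherapy CT volumes and deformable
    accumulation of dose across treatment fractions, aimed at combined
    external-beam (EBRT) and high-dose-rate brachytherapy (HDR-BT) courses.
    Provides volume and dose-grid I/O (NIfTI, MetaImage, DICOM CT series and
    RTDOSE), median-filter preprocessing, closed-form point-set rigid and
    affine fits, intensity-driven rigid, affine and multi-resolution B-spline
    free-form deformation (FFD) registration under normalized mutual
    information, a landmark-constrained FFD restricted to a region of interest
    for locally large deformations, pull-back dose warping with voxelwise
    accumulation, and a synthetic pelvic phantom generator with known
    ground-truth deformations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
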