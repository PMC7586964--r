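Package: rapsreg
Title: Radiology-Pathology Slice Registration for Prostate Whole-Mount Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Registers serial whole-mount prostate histopathology sections to
    T2-weighted MRI. Reconstructs the pre-sectioning 3D histology stack by
    chaining pairwise rigid registrations outward from the middle slice,
    aligns each MRI slice to its corresponding histology slice with a masked
    affine registration followed by a free-form (cubic B-spline) deformable
    registration driven by Mattes mutual information over a three-level
    multi-resolution pyramid, and projects cancer labels and anatomic
    landmarks onto the MRI grid through the composite transform. Includes a
    digital prostate phantom that simulates histologic processing artifacts
    (per-slice rotation, shrinkage, translation, imperfect slice
    correspondence) with known ground-truth transforms, and evaluation
    metrics (slice-averaged Dice overlap, boundary Hausdorff distance,
    landmark and urethra center-of-mass deviations).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    png,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
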