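Package: gbmGrowth
Title: Glioblastoma Growth Direction Analysis Against White-Matter Fiber
    Orientation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates voxel-wise tumor growth vector fields from pairs of
    longitudinal contrast-enhanced T1-weighted MRI volumes and compares them
    against white-matter principal fiber directions from a diffusion-tensor
    atlas. Provides intra-patient affine alignment, non-linear tumor-region
    registration yielding a localized deformation field, affine template
    normalization with finite-strain vector reorientation, folded angle maps
    in [0, 90] degrees, parallel/perpendicular growth classification, an
    exact Wilcoxon signed-rank test for cohort-level dominance of
    fiber-aligned growth, tumor volumetry with slice-gap correction, lesion
    frequency maps, and a synthetic longitudinal phantom generator with
    known ground-truth growth directions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'alignment.R'
    'cohort-stats.R'
    'gbmGrowth-package.R'
    'geometry.R'
    'io.R'
    'normalization.R'
    'phantom.R'
    'pipeline.R'
    'registration.R'
    'volumetry.R'
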