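Package: gfdemons
Title: Demons Deformable Registration with Supervoxel-Guided Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deformable (Demons) registration of 3-D medical volumes in which
    the classical isotropic Gaussian regularization of the displacement field
    can be replaced by linear-time guided image filtering driven by supervoxel
    (SLIC) guidance images, preserving sliding-motion discontinuities at organ
    interfaces without prior segmentation. Provides symmetric sum-of-squared-
    differences and local-correlation-coefficient forces, single- and
    multi-channel guided filtering with an explicit kernel-weight oracle,
    random-perturbation and multiscale supervoxel guidance, a multiresolution
    driver, NIfTI and MetaImage volume input/output, a synthetic sliding-motion
    phantom, and landmark-based target registration error evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
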