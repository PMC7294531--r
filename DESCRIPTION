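Package: vesselmold
Title: 3D-Printable Hollow Vascular Models from CT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fabrication pipeline turning contrast-enhanced CT volumes into
    printable hollow vascular models: intensity histograms over an aneurysm
    region, partial-volume threshold selection midway between the lumen
    intensity peak and an assumed 80 HU tissue background, connected-object
    lumen segmentation with 0/255 binarization, mask inversion into a
    bounded solid (or thin shell) with sheath ports, and watertight
    iso-surface extraction at level 128 exported as STL.  Includes a
    synthetic vascular-phantom generator with exact ground truth, readers
    and writers for DICOM series, NIfTI and MetaImage volumes, and mesh
    printability validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
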