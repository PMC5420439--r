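Package: mcmf
Title: Superpixel Multichannel Multifeature Detection of Retinal Red Lesions
Version: 0.1.0
Authors@R: person("Alex", "Carver", email = "alex.carver@example.org",
    role = c("aut", "cre"))
Description: Detects red lesions (microaneurysms and hemorrhages) in color
    fundus photographs for diabetic retinopathy screening. Candidate regions
    are extracted with SLIC superpixel segmentation of a CLAHE-enhanced image,
    described by a 31-dimensional feature vector built from seven derived
    image channels plus global and contextual statistics, and classified with
    Fisher discriminant analysis. Morphological postprocessing removes false
    positives on the vasculature (multiscale vessel map with logical-OR
    fusion) and at the fovea. Includes image-based and pixel-based (connected
    component overlap) evaluation, ROC/AUC utilities, and a seeded synthetic
    fundus phantom generator with per-pixel ground truth for end-to-end
    testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    jpeg,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
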