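Package: fakir3d
Title: Fakir Line-Probe Stereology and Watershed Morphometry for 3D Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates volumes and surface areas of 3D binary masks with the
    Fakir method: lattices of parallel line probes in one, three, or seven
    directions under a shared Haar-uniform random rotation, with mutually
    staggered grids and antithetic variance reduction. Includes Monte-Carlo
    analysis of the orientation-induced coefficient of variation for planar
    (worst-case) objects and optimisation of seven-fold probe weights; a
    marker-controlled priority-flood watershed stage for extracting cavity
    spaces (such as the endoneurocranium) from CT-like scalar volumes, with
    Otsu bone thresholding, Euclidean distance reliefs, and morphological
    closing to seal foramina; downstream morphometry statistics (compartment
    fractions, group summaries, sexual-dimorphism contrasts, method
    agreement, correlation); synthetic phantoms with analytic ground truth;
    and NIfTI/MetaImage/CSV input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
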