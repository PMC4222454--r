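Package: uptake3d
Title: Absolute Nanoparticle Counting and Subcellular Localization from
    Two-Channel 3D Fluorescence Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies nanoparticle uptake by single cells from two-channel
    3D confocal z-stacks. The membrane channel yields a 3D cell
    reconstruction split into intracellular, membrane-shell and
    extracellular regions by an anisotropy-aware Euclidean distance
    transform; diffraction-limited particle objects are detected in the
    particle channel as 3D connected components and converted to absolute
    particle numbers by comparing their integrated intensity with the mean
    single-particle intensity measured in a coverslip calibration. Includes
    a synthetic two-channel stack generator with ground truth, per-cell
    statistics (mean, SEM, unpaired Student's t-test) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
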