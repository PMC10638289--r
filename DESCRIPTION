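Package: chp
Title: Chromatin Homology Profiles for Nuclear Texture Analysis in Cytology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies nuclear chromatin patterns in cytology photomicrographs
    by topological data analysis. A binarization threshold is swept over all
    256 grey levels of a nucleus image and the one-dimensional Betti number
    (count of holes enclosed by chromatin) is recorded at each step, yielding a
    chromatin homology profile. From the profile the package derives b1MAX
    (the profile maximum), the homology value HV (first threshold at which the
    hole count reaches 5), and the chromatin density b1MAX/ns^2, together with
    brightness normalization (modal-intensity correction and group median
    offsets) and a fixed-cutoff histotype classifier for lung cytology
    (small-cell vs non-small-cell vs adenocarcinoma/squamous). Includes a
    synthetic nucleus generator with analytically known topology for
    validation, readers for PNG/TIFF images with separate nucleus masks, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
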