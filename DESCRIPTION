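Package: ddrphenokit
Title: Quantitative Phenotyping for DNA Damage Response Imaging and Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying DNA damage response phenotypes from
    fluorescence microscopy and plate assays: nucleus detection by multiscale
    Laplacian-of-Gaussian blob detection, foreground thresholding and seeded
    flood-fill splitting of under-segmented cell regions, moment-based cell
    shape metrics (eccentricity, isoperimetric roundness) with DBSCAN
    morphology classification, per-nucleus damage-foci counting with mitotic
    exclusion, four-parameter log-logistic and three-parameter exponential
    decay dose-response fitting with AIC model selection and ED50 estimation,
    exponential growth doubling-time estimation, wound-closure and gel-lane
    fragmentation quantification, and multiplicity-corrected group
    comparisons. A synthetic scene and assay-table generator with exact ground
    truth makes every stage testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
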