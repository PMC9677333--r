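Package: protonrad
Title: Image-Guided Small-Animal Proton Irradiation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational side of image-guided proton
    irradiation of small animals with a flat-panel detector: dark- and
    beam-background correction and median stacking of detector frames,
    image-quality metrics (SNR, CNR, edge-enhancement FWHM, line-pair
    resolution, detectability versus dose), two-dimensional treatment-plan
    projections with Jaccard observer-agreement statistics, landmark-based
    similarity-transform registration of plan and radiograph with
    stage-coordinate output and daily-QA verification, and gammaH2AX/DAPI
    DNA-damage tile maps correlated with a dose distribution. A synthetic
    data generator produces phantoms, collimator and mouse radiographs,
    label volumes, nuclei image pairs and an analytic depth-dose curve,
    each with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
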