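Package: vesica
Title: Bladder DWI Phantoms, U-Net Ensemble Segmentation, and Radiomics
    Reproducibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates diffusion-weighted bladder MRI phantoms (b=0 and
    b=1000 s/mm2 images plus apparent diffusion coefficient maps built from a
    mono-exponential decay model) with known tumor ground truth, trains a
    five-level U-Net segmentation network with Dice loss under five-fold
    patient-level cross-validation, fuses the five fold models by per-voxel
    majority vote (at least 3 of 5), evaluates overlap with the Dice
    similarity coefficient, extracts the 107 standard radiomics features
    (first-order, shape, GLCM, GLRLM, GLSZM, NGTDM, GLDM) from ADC maps with
    fixed-bin-width discretization, and quantifies manual-versus-automatic
    feature reproducibility with the two-way random-effects intraclass
    correlation coefficient ICC(2,1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
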