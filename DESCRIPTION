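Package: adipostereo
Title: Design-Based Stereology and Light-Sheet Volumetry of Adipose Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unbiased quantitative morphology of unilocular adipocytes:
    stereological probes (point counting, Gundersen unbiased counting frames,
    physical and optical disectors), numerical volume densities with tissue
    shrinkage correction, voxel-based single-cell volumetry in light-sheet
    style 3D image stacks, microbead imaging quality control, and depot-level
    derived quantities (total and mean adipocyte volumes and numbers). A
    synthetic tissue-phantom generator based on Laguerre tessellations
    provides membrane-labelled adipose stacks, nucleus-bearing serial section
    series and bead stacks with exhaustive ground truth, so every estimator
    is testable end to end without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
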