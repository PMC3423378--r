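Package: fibrinet
Title: Quantitative Image Analysis of Fibrin Clot Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying fibrin network microstructure in
    fluorescence micrographs of plasma clots. Fibers are detected by
    stereological test-line sampling of intensity profiles, measured for
    local-maximum intensity and full-width-at-half-maximum diameter, and
    summarised as density (fibers/100 um), a thin-to-thick diameter ratio
    derived from a bimodal Gaussian-mixture fit, trifunctional branch
    junctions (width conservation), crossing-fiber contacts (proportional
    intensity increase), clot void area and volume from binarized slice
    stacks, and densities of abnormal fibrin clusters and agglomerates.
    Includes a synthetic fibrin-scene generator with complete ground truth
    for validating every measurement, and a consolidated per-clot read-out
    report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
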