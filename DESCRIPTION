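Package: retess
Title: Density-Based Relative Enrichment Colocalization for SMLM Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coordinate-based colocalization analysis for two-colour
    single-molecule localization microscopy (SMLM) in 2D and 3D. The reference
    channel is partitioned into Voronoi regions around its localizations; each
    region is scored by the ratio of observed to expected counts of the primary
    channel (relative enrichment, RE) and the scores are summarised across the
    reference density distribution by binning on mean neighbour distance or log
    region measure. Includes point-pattern simulators for validation, per-image
    condition statistics with familywise error control, and RE colour-coded
    region and point visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RANN,
    sp,
    data.table,
    ggplot2,
    scales,
    jsonlite,
    pracma,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deldir,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
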