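Package: seedshape
Title: Seed Silhouette Morphometrics and Outline-Group Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of seed silhouettes from calibrated
    photographs or binary masks. Computes the standard planar shape
    descriptors (area, perimeter, fitted-ellipse axes, aspect ratio,
    circularity, roundness, solidity), builds per-species average
    silhouettes by aligned mask stacking, measures similarity of outlines
    to cardioid-derived geometric seed models (J index), and compares
    ornamentation groups (smooth, rugose, echinate, papillose) with
    Kruskal-Wallis tests followed by Campbell-Skillings step-down
    homogeneous subsets and a compact letter display. Includes a synthetic
    seed generator so the full pipeline can be exercised without real
    images.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    png,
    isoband,
    igraph,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    sp
Config/testthat/edition: 3
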