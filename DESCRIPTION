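Package: vesselmorph
Title: Morphometry of Endothelial Cells on Tubular Vessels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unrolls 3D-traced endothelial cell boundaries on tubular blood
    vessels into the plane, extracts per-cell shape parameters (area,
    perimeter, elongation, angle of alignment), measures vessel diameters
    and proliferation rates, and compares cell populations with normalized
    UMAP embeddings and a kernel-density Jensen-Shannon divergence in the
    original four-dimensional shape space. Includes a synthetic-data
    generator that builds vessels tessellated into cells with closed-form
    ground truth, so every stage of the pipeline can be verified without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    uwot
Suggests:
    FNN,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
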