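Package: luadmorph
Title: Cellular Potts Simulation and Morphometrics of Lung Adenocarcinoma Growth Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compartmental cellular Potts model (CPM) of lung adenocarcinoma
    (LUAD) morphogenesis, with named parameter presets that reproduce the five
    histologic growth patterns (lepidic, acinar, papillary, micropapillary,
    solid) from a common base model, cell-contact morphology metrics that score
    and classify simulated tissue architecture, and the accompanying image and
    spot quantification statistics: spheroid shape index from binary masks,
    marker-positive pixel ratios, and 3D nearest-neighbour distance statistics
    with pooled two-sample tests computed from group totals. Includes a
    synthetic-data module that generates lattices, masks, and point sets with
    known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
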