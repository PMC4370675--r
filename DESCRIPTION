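Package: leukogate
Title: Hierarchical Gating, Absolute Counting and Radar Projection for
    10-Color Leukocyte Immunophenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, tested toolkit for quantifying the major human leukocyte
    populations from 10-color flow cytometry. Implements a registry of eight
    published staining panels, hierarchical non-overlapping gating trees
    (TBNK/M/G, Myeloid, Monocytes-1/-2), data-driven threshold placement from
    fluorescence-minus-one (FMO) controls and in-tube negative populations,
    single-platform bead-based absolute cell counting, region-based myeloid
    phenotype classification (including CD123+ immature myeloid cells/MDSCs),
    and star-coordinate ("radar") projection of up to 13 marker axes. Ships a
    seeded synthetic whole-blood/bone-marrow/pleural-fluid simulator with
    per-event ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
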