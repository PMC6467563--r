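Package: cerefold
Title: Mechanics and Morphometrics of Cerebellar Folding Initiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how folds initiate in the developing
    cerebellum from midsagittal sections. Implements contour-based
    morphometrics (external granule layer length, core area, folding index,
    thickness profiles, shape factor, sphericity), a multi-phase variational
    model of a fluid-like outer layer under radial and circumferential
    constraints with an independent constrained Fourier minimizer, the
    classical elastic bilayer wrinkling baseline, anchoring-center windowed
    proliferation and fiber-density quantification, and seeded synthetic-data
    generators carrying machine-readable ground truth.
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
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
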