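Package: particledose
Title: Comparative Nanoparticle Dosimetry for Cell Culture and Inhalation Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for placing in vitro and in vivo nanoparticle toxicity data
    on a common target-cell dose scale. Implements a one-dimensional
    sedimentation-diffusion transport model of particle delivery to cells in
    liquid culture (with fractal-agglomerate effective density), fitting of
    saturable cell-association fractions, allocation of inhaled lung burden to
    airway generations with per-surface-area and per-macrophage dose metrics,
    single-phase particle clearance fitting, occupational exposure-limit
    extrapolation to the human lung, and interval-based comparison of
    effective dose bands across exposure systems. Includes seeded
    synthetic-data generators emulating the measurement structure of each
    pipeline input so that every stage is testable without external data.
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
    Matrix,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
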