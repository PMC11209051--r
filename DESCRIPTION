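Package: echotestis
Title: Quantitative Ultrasound Echotexture Analysis of Testicular Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for tracking testicular maturation in growing dogs from
    B-mode and colour-Doppler ultrasound. Quantifies parenchymal echotexture
    with the spot-meter (nine 2 mm^2 regions of interest) and region-area
    (whole-parenchyma, mediastinum excluded) techniques, computes
    percent-echogenicity standardization ratios against the tunica albuginea
    and mediastinum testis, assigns modified Gumbsch colour-Doppler
    vascularity scores (0-4) by connected-component analysis of flow
    overlays, derives ellipsoid testicular volumes and semen quantities
    (haemocytometer concentration, total sperm count, fertility threshold),
    stages puberty from longitudinal milestones, and runs the rank-based
    statistical battery (Spearman correlation matrix, lagged
    echogenicity-versus-sperm correlations, Kruskal-Wallis comparisons,
    grayscale-intensity slope fits, plateau detection, maturity-indicator
    panel). A seeded synthetic-cohort generator emulates the longitudinal
    study design (eight dogs, biweekly exams from week 4 to 40) including
    speckle-textured B-mode frames with region masks, so the entire pipeline
    is testable without image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
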