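Package: gelplate
Title: Quasi-Static Meniscus Modelling and Image Analysis for Thin
    Hydrogels in Multiwell Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the dispensing and re-aspiration of hydrogel precursor
    solutions in cylindrical multiwell-plate wells with a quasi-static
    axisymmetric Young-Laplace solver including contact-angle hysteresis,
    and computes flatness and radial-coverage metrics of the resulting
    air-liquid interface together with a robustness sweep over volume and
    well-radius tolerances.  Companion image-analysis pipelines classify
    per-well quality-control z-stacks (planar, concave, wall-contact,
    empty), extract gel height maps and thickness/flatness summaries,
    quantify cell confluency from label-free time-lapse movies with
    four-parameter log-logistic IC50 fitting, and score FUCCI cell-cycle
    states with mitotic detection and gap-closing track linking.  Seeded
    synthetic-data generators provide phantoms with ground truth for every
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
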