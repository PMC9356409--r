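Package: budtrack
Title: Tracking, Pedigree Annotation and Quantification for Budding-Yeast
    Label Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Headless analysis of integer-labeled segmentation-mask movies
    from budding-yeast live-cell imaging. Provides frame-to-frame tracking
    by intersection-over-area overlap, automatic separation of merged
    objects by convexity-defect detection on simplified contours,
    mother-bud pairing as a minimum-cost bipartite matching on
    contour-to-contour distances, a cell-cycle annotation table with
    automatic propagation of division annotations and pairing corrections
    to past and future frames, cell-volume estimation from 2D masks by
    solid-of-revolution integration, background-corrected fluorescence
    quantification, multiple-object-tracking benchmark metrics (MOTA and
    link F-score), and a deterministic synthetic-colony generator with
    ground-truth pedigrees and controlled perturbations for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    clue,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
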