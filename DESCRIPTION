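Package: pamp
Title: Primary Assessment of Migrastatic Potential from Quantitative Phase Imaging Time-Lapse
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening candidate migrastatic drugs with label-free
    quantitative phase imaging (QPI) time-lapse microscopy. Converts phase maps
    (radians) to dry-mass density, segments and tracks adherent cells, computes
    per-cell morphometry (mass, area, perimeter, circularity, weighted centre
    of gravity) and migration dynamics (speed, path length, Euclidean
    displacement, meandering index), classifies invasive phenotypes by a
    displacement/directionality quadrant rule, and compares treated versus
    control conditions with a variance-gated two-sample t-test. Includes a
    persistent-random-walk synthetic movie generator with ground truth, and an
    optional off-axis hologram forward model with Fourier sideband phase
    reconstruction, so the whole pipeline is testable without microscope data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
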