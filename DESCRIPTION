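Package: scanbody
Title: Congruence Analysis of Implant Scanbody Meshes Against Library Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying the dimensional congruence between
    triangle-mesh surface reconstructions of dental implant scanbodies
    (as captured by intraoral scanners) and the manufacturer's exact CAD
    library file. Provides mesh input/output for STL, PLY and OBJ,
    generation of synthetic scanbody meshes with controlled scanner error
    models, two-stage rigid registration (three-point landmark alignment
    followed by robust point-to-plane iterative closest point), signed
    point-to-surface deviation fields with colorimetric banding and
    region-wise direction labels, and the hierarchical statistical
    battery used in scanner comparison studies: balanced scanner
    estimates with Tukey-adjusted pairwise contrasts, within-scanner
    scanbody contrasts, Friedman rank tests with Holm correction, and
    agglomerative hierarchical biclustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
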