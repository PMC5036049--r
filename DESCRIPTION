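Package: crhunter
Title: Catalytic Residue Prediction from Structure and Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts catalytic residues in enzyme structures by fusing
    four per-residue predictors: a structural and a sequence support
    vector machine built on Delaunay-tessellation contact descriptors,
    residue interaction network centralities, multi-scale Laplacian
    norms and evolutionary profiles, plus two template predictors that
    transfer annotations from the most similar reference enzyme found
    by structure or profile alignment. Includes a Delaunay/Voronoi
    residue contact graph engine, evaluation utilities (ROC AUC, MCC,
    grouped cross-validation) and a synthetic benchmark generator for
    end-to-end testing without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    e1071,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
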