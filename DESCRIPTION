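Package: csfgraph
Title: Graph-Based Matrix Elements Between Genealogical Configuration
    State Functions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes matrix elements of arbitrary second-quantized operator
    sequences between spin-adapted configuration state functions (CSFs) built
    in the genealogical coupling scheme, without expanding the CSFs into
    Slater determinants.  CSFs are represented as two-dimensional lattice
    graphs (genealogical determinant graphs) whose root-to-end paths encode
    the determinant expansion; operator sequences act directly on a compact
    graph state and matrix elements are obtained by a level-by-level overlap
    sweep.  Includes exact arithmetic over signed square roots of rationals,
    an explicit determinant-expansion oracle for verification, and a seeded
    benchmark harness comparing both engines.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
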