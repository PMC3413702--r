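Package: boolsig
Title: Boolean Modelling of Cell Signalling Networks by Integer Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles curated descriptions of signal transduction networks into
    systems of Boolean statements in which inhibitors block individual
    signalling events rather than deactivating signals, translates the
    statements into binary integer programs, and answers Minimum Input,
    Output Maximization, and Minimal Input Sets queries by exact optimization
    with integer cuts. Includes semi-automatic curation of strongly connected
    components (catalysis and complex-dissociation motifs), dependency-graph
    statistics, BioPAX Level 3 and plain-text model input, GML export for
    visual curation in Cytoscape, and deterministic generators of synthetic
    signalling systems for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    xml2,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
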