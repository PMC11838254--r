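Package: fibrilbind
Title: Cooperative Nearest-Neighbor Ligand Binding to Protein Fibrils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-mechanical model of symmetric small-molecule binding
    to the linear array of equivalent sites on a protein fibril (e.g. tau
    paired helical filaments), with nearest-neighbor ligand-ligand
    cooperativity.  Provides closed-form saturation and saturated-competition
    binding isotherms and their midpoint relations, exact transfer-matrix
    occupancies for finite and infinite fibrils, bound-count distributions,
    a seeded heat-bath Monte Carlo simulator, nonlinear regression of the
    model to saturation and competition assay data (counts per minute),
    identifiability diagnostics, detection-limit calculations for PET
    tracers, and a synthetic-dataset generator with the assay signal model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
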