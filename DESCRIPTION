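Package: mtMisalign
Title: Misalignment-Length Signatures of Mitochondrial DNA Deletion
    Breakpoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the distribution of DNA misalignment lengths associated
    with a catalog of mitochondrial DNA deletion breakpoints.  Nearest-
    neighbor hybridization thermodynamics give the partition function of
    duplex formation between L-strand and H-strand segments around each
    breakpoint; binned misalignment propensities over a window of analysis
    are combined in a finite mixture model over a grid of duplex lengths
    (0-100 nt), fitted by maximum likelihood with parametric-bootstrap
    uncertainty.  Includes a simulator for synthetic circular genomes and
    in-silico breakpoint catalogs with known mixture structure.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
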