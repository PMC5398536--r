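Package: coevodock
Title: Coevolution-Guided Docking of Protein Heterocomplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds models of two-chain protein complexes guided by residue
    coevolution. Implements mean-field direct coupling analysis (DCA) of a
    domain-family alignment (sequence reweighting, pseudocounted frequency
    estimation, covariance inversion, direct-information scoring), filtering
    of coupled pairs against monomer-fold contacts, solvent burial and known
    homodimer interfaces, and restrained docking of two protomers by
    simulated-annealing Langevin dynamics on C-alpha structure-based (Go-type)
    models under flat-bottom coupling restraints and a metal-cluster proximity
    restraint. Includes synthetic generators (Potts-sampled alignments with
    planted couplings, toy bead-chain complexes with known geometry) for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    bio3d,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
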