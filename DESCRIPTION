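Package: cgfold
Title: Machine-Learned Coarse-Grained Protein Force Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates machine-learned coarse-grained (CG) protein
    force fields with one alpha-carbon bead per residue. Provides the linear
    CG mapping of all-atom coordinate/force data, fitted prior potentials
    (harmonic bonds, power-law repulsion, chirality-breaking dihedrals), a
    graph neural-network potential with continuous-filter convolutions
    trained by variational force matching against mapped forces
    (delta-learning over the priors), a BAOAB Langevin simulator for the
    combined potential, and a Markov-state-model validation pipeline
    (pairwise-distance features, TICA, k-means, reversible MSM estimation,
    PCCA+ macrostates, free-energy surfaces, Kabsch RMSD, bootstrapped
    native-state reports). Ships a synthetic toy-polymer fixture generator
    with exact analytic forces so the whole pipeline can be exercised and
    tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    yaml,
    bio3d
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
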