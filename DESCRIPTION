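Package: rampfold
Title: Force-Ramp Single-Molecule Analysis of Hierarchical G-Quadruplex
    Unfolding
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse optical-tweezers force-ramp
    experiments on higher-order G-quadruplex structures such as those in
    the human telomerase (hTERT) promoter: worm-like-chain polymer models
    and a calibrated change-in-contour-length to nucleotide conversion, a
    Bell-Evans rupture simulator with hierarchical species, cooperative
    unfolding and refolding heterogeneity, rupture-event detection with
    Delta-L estimation and single-tether fingerprint checks, kernel
    resampling deconvolution of Delta-L populations at nanometre
    resolution, unfolding-pathway reconstruction as transition graphs,
    and Jarzynski nonequilibrium free-energy estimation of tertiary
    stabilisation energies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
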