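Package: dsbmd
Title: Coarse-Grained Dynamic Structure-Based Simulations of Gluten-Like
    Protein Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A one-bead-per-residue implicit-solvent Langevin simulator for
    dense systems of intrinsically disordered storage proteins such as wheat
    gluten.  Inter-residue contacts form and break dynamically based on the
    instantaneous backbone geometry (backbone-backbone, backbone-sidechain
    and sidechain-sidechain contacts, plus reversible disulfide bridges and
    optional static Go-type contacts for structured domains).  The package
    provides a wall-driven rheology protocol (compression to melt density,
    oscillatory shear or normal strain, uniaxial extension) and an analysis
    suite: dynamic shear modulus G'/G''/tan delta, maximum stretching force
    and work, inter-chain contact counts, coordination numbers, RMSF, chain
    distortion, primitive-path entanglement counts and grid-probe cavity
    volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    pracma,
    knitr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
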